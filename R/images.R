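#' Configuration for synthetic bright-field droplet images
#'
#' Describes the rendering of synthetic droplet micrographs with known ground
#' truth: bright circular droplets (interior above background, a brighter
#' rim) placed without overlap on a darker noisy background. Occupied
#' droplets additionally carry a high-spatial-frequency granular texture over
#' their interior, emulating the speckled appearance of a grown microcolony
#' under bright field; empty droplets stay smooth apart from sensor noise.
#'
#' Grey-level amplitudes are expressed in 8-bit grey levels (0-255) for
#' intuition and scaled internally to the [0, 1] pixel range. Defaults place
#' 100 droplets of radius 18 +/- 2 px per 960 x 960 image (large enough that
#' the square inscribed in a droplet holds a full 16 x 16 texture patch),
#' with occupancy
#' 0.091 (the single-cell fraction of the Poisson design) and a granular
#' texture SD of 10 grey levels against a background noise SD of 2 (a 5x
#' contrast-to-noise ratio).
#'
#' @param image_size `c(height, width)` in pixels.
#' @param droplet_radius `c(mean, sd)` of droplet radii in pixels; radii are
#'   truncated to mean +/- 3 sd and floored at 3 px.
#' @param n_droplets_per_image droplets per image.
#' @param n_images number of images to render.
#' @param occupancy_prob probability a droplet contains a grown microcolony.
#' @param texture_contrast SD of the granular interior signal of occupied
#'   droplets, in grey levels (>= 0).
#' @param background_noise_sd SD of global Gaussian sensor noise, grey levels.
#' @param seed integer seed (`NULL`: current RNG state).
#' @return an `image_config` list.
#' @export
image_config <- function(image_size = c(960L, 960L),
                         droplet_radius = c(mean = 18, sd = 2),
                         n_droplets_per_image = 100L,
                         n_images = 20L,
                         occupancy_prob = 0.091,
                         texture_contrast = 10,
                         background_noise_sd = 2,
                         seed = NULL) {
  if (length(image_size) != 2L || any(image_size < 16)) {
    stop("image_size must be c(height, width), each >= 16")
  }
  if (droplet_radius[1] <= 0 || droplet_radius[2] < 0) {
    stop("droplet_radius mean must be > 0 and sd >= 0")
  }
  if (n_droplets_per_image < 1) stop("n_droplets_per_image must be >= 1")
  if (n_images < 1) stop("n_images must be >= 1")
  if (occupancy_prob < 0 || occupancy_prob > 1) {
    stop("occupancy_prob must be in [0, 1]")
  }
  if (texture_contrast < 0) stop("texture_contrast must be >= 0")
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  structure(list(
    image_size = as.integer(image_size),
    droplet_radius = c(mean = unname(droplet_radius[1]),
                       sd = unname(droplet_radius[2])),
    n_droplets_per_image = as.integer(n_droplets_per_image),
    n_images = as.integer(n_images),
    occupancy_prob = occupancy_prob,
    texture_contrast = texture_contrast,
    background_noise_sd = background_noise_sd,
    seed = seed
  ), class = "image_config")
}

# rendering grey levels ([0,1] scale)
.render_levels <- list(background = 0.35, interior = 0.55, rim = 0.80)

#' Generate synthetic droplet images with a ground-truth manifest
#'
#' Renders `n_images` bright-field-like micrographs per [image_config()].
#' Droplets are laid out on a jittered grid so that no two droplets overlap
#' and every droplet lies fully inside the image; if the requested number of
#' droplets cannot fit at the maximal radius, generation fails with an
#' explicit error rather than silently packing fewer. Occupancy is Bernoulli
#' per droplet; occupied droplets receive `n_cells` from a zero-truncated
#' Poisson(0.1) (the conditional cell count of the encapsulation design).
#'
#' @param config an [image_config()].
#' @return list with `images` (list of numeric matrices in [0, 1], rows = y)
#'   and `manifest` (data.frame: `image`, `droplet_id`, `cx`, `cy`, `r`,
#'   `occupied`, `n_cells`; centers are 0-based pixel coordinates, x =
#'   column).
#' @export
generate_droplet_images <- function(config) {
  stopifnot(inherits(config, "image_config"))
  run <- function() {
    H <- config$image_size[1]; W <- config$image_size[2]
    rmean <- config$droplet_radius["mean"]; rsd <- config$droplet_radius["sd"]
    rmax <- rmean + 3 * rsd
    n <- config$n_droplets_per_image
    nx <- ceiling(sqrt(n * W / H))
    ny <- ceiling(n / nx)
    cw <- floor(W / nx); ch <- floor(H / ny)
    pad <- 2  # clearance between a droplet and its cell border
    if (min(cw, ch) < 2 * (rmax + pad)) {
      stop("cannot place ", n, " droplets of max radius ", round(rmax, 1),
           " px without overlap in a ", H, "x", W, " image")
    }
    noise <- config$background_noise_sd / 255
    contrast <- config$texture_contrast / 255

    images <- vector("list", config$n_images)
    manifest <- vector("list", config$n_images)
    for (im in seq_len(config$n_images)) {
      img <- matrix(.render_levels$background, nrow = H, ncol = W)
      if (noise > 0) img <- img + matrix(stats::rnorm(H * W, 0, noise), H, W)

      cells <- sample.int(nx * ny, n)
      radii <- pmax(3, pmin(rmax, pmax(rmean - 3 * rsd,
                                       stats::rnorm(n, rmean, rsd))))
      occupied <- stats::runif(n) < config$occupancy_prob
      n_cells <- integer(n)
      if (any(occupied)) {
        # zero-truncated Poisson(0.1) via rejection (lambda small, cheap)
        n_cells[occupied] <- vapply(which(occupied), function(i) {
          k <- 0L
          while (k == 0L) k <- stats::rpois(1L, 0.1)
          k
        }, integer(1))
      }
      cx <- cy <- numeric(n)
      for (i in seq_len(n)) {
        gx <- (cells[i] - 1L) %% nx
        gy <- (cells[i] - 1L) %/% nx
        r <- radii[i]
        # jitter keeps the circle inside its grid cell (hence no overlap)
        cx[i] <- gx * cw + stats::runif(1, r + pad, cw - r - pad)
        cy[i] <- gy * ch + stats::runif(1, r + pad, ch - r - pad)
        img <- draw_droplet(img, cx[i], cy[i], r, occupied[i], contrast)
      }
      img[img < 0] <- 0; img[img > 1] <- 1
      images[[im]] <- img
      manifest[[im]] <- data.frame(
        image = im, droplet_id = seq_len(n),
        cx = cx, cy = cy, r = radii,
        occupied = occupied, n_cells = n_cells
      )
    }
    list(images = images, manifest = do.call(rbind, manifest))
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# paint one droplet (1-based pixel grid internally; cx/cy are 0-based)
draw_droplet <- function(img, cx, cy, r, occupied, contrast) {
  H <- nrow(img); W <- ncol(img)
  rows <- max(1L, floor(cy + 1 - r)):min(H, ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(W, ceiling(cx + 1 + r))
  d <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+"))
  interior <- d <= r - 1.5
  rim <- d > r - 1.5 & d <= r
  sub <- img[rows, cols]
  sub[interior] <- .render_levels$interior
  sub[rim] <- .render_levels$rim
  if (occupied && contrast > 0) {
    n_int <- sum(interior)
    sub[interior] <- sub[interior] + stats::rnorm(n_int, 0, contrast)
  }
  img[rows, cols] <- sub
  img
}

#' Write synthetic droplet images and their manifest to disk
#'
#' Images are written as 16-bit grayscale TIFF (default) or 8-bit PNG, one
#' file per image (`image_001.tif`, ...); the ground-truth manifest goes to
#' `manifest.csv` alongside.
#'
#' @param generated output of [generate_droplet_images()].
#' @param dir output directory (created if absent).
#' @param format `"tiff"` or `"png"`.
#' @return invisibly, the vector of image file paths.
#' @export
write_droplet_images <- function(generated, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- vapply(seq_along(generated$images), function(i) {
    p <- file.path(dir, sprintf("image_%03d.%s", i, ext))
    if (format == "tiff") {
      tiff::writeTIFF(generated$images[[i]], p, bits.per.sample = 16L)
    } else {
      png::writePNG(generated$images[[i]], p)
    }
    p
  }, character(1))
  utils::write.csv(generated$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(paths)
}

#' Read droplet images (and manifest, if present) from a directory
#'
#' @param dir directory of grayscale TIFF/PNG images as written by
#'   [write_droplet_images()].
#' @return list with `images` (numeric matrices in [0, 1]) and `manifest`
#'   (data.frame or `NULL`).
#' @export
read_droplet_images <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0L) stop("no TIFF/PNG images found in ", dir)
  images <- lapply(files, function(f) {
    img <- if (grepl("png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) img <- img[, , 1]  # drop extra channels
    img
  })
  mf <- file.path(dir, "manifest.csv")
  manifest <- if (file.exists(mf)) utils::read.csv(mf) else NULL
  list(images = images, manifest = manifest)
}
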