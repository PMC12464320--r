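#' Detect droplets in a grayscale bright-field image
#'
#' Droplets render as bright discs on a darker background, so detection
#' proceeds by Otsu thresholding followed by connected-component labeling
#' (EBImage). Each blob's centroid gives the droplet center and its area the
#' equivalent circle radius; blobs failing a compactness gate (a pixel
#' farther from the centroid than `1.2 * r`, as happens when two droplets
#' merge into one blob) are rejected, as are blobs whose bounding circle is
#' not fully inside the image (droplets cut by the frame) or whose radius
#' falls outside `[min_radius, max_radius]`. Detections overlapping an
#' already-accepted (larger) detection by more than `max_overlap` of the sum
#' of radii are dropped.
#'
#' @param image numeric matrix in [0, 1] (rows = y).
#' @param min_radius,max_radius radius acceptance band in pixels.
#' @param threshold grey-level cut separating droplets from background;
#'   `NULL` = Otsu's threshold.
#' @param max_overlap maximal tolerated center-distance shortfall, as a
#'   fraction of `r1 + r2`.
#' @return data.frame with `droplet_id`, `cx`, `cy` (0-based pixel
#'   coordinates, x = column), `r` (pixels). Zero rows for blank images.
#' @export
detect_droplets <- function(image, min_radius = 5, max_radius = Inf,
                            threshold = NULL, max_overlap = 0.1) {
  stopifnot(is.matrix(image), min_radius > 0, min_radius < max_radius)
  empty <- data.frame(droplet_id = integer(0), cx = numeric(0),
                      cy = numeric(0), r = numeric(0))
  if (diff(range(image)) < 1e-6) return(empty)  # uniform image: nothing there
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(t(image)), range = c(0, 1))
  }
  mask <- image > threshold
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  lab <- t(EBImage::imageData(lab))
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  labs <- lab[idx]
  H <- nrow(image); W <- ncol(image)

  dets <- lapply(split(seq_along(labs), labs), function(ii) {
    ry <- rows[ii]; cx_ <- cols[ii]
    cy <- mean(ry) - 1; cx <- mean(cx_) - 1
    area <- length(ii)
    r <- sqrt(area / pi)
    if (r < min_radius || r > max_radius) return(NULL)
    dmax <- sqrt(max((ry - 1 - cy)^2 + (cx_ - 1 - cx)^2))
    if (dmax > 1.2 * r) return(NULL)  # not compact: likely merged blobs
    # boundary rule: droplet must lie fully inside the frame
    if (cx - r < 0 || cx + r > W - 1 || cy - r < 0 || cy + r > H - 1) {
      return(NULL)
    }
    c(cx = cx, cy = cy, r = r)
  })
  dets <- do.call(rbind, dets[!vapply(dets, is.null, logical(1))])
  if (is.null(dets) || nrow(dets) == 0L) return(empty)
  dets <- as.data.frame(dets)
  dets <- dets[order(-dets$r), , drop = FALSE]
  keep <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    d <- sqrt((dets$cx[prior] - dets$cx[i])^2 +
              (dets$cy[prior] - dets$cy[i])^2)
    if (any(d < (dets$r[prior] + dets$r[i]) * (1 - max_overlap))) {
      keep[i] <- FALSE
    }
  }
  dets <- dets[keep, , drop = FALSE]
  data.frame(droplet_id = seq_len(nrow(dets)), cx = dets$cx, cy = dets$cy,
             r = dets$r, row.names = NULL)
}

#' Mean GLCM feature point of one droplet
#'
#' Tiles the axis-aligned square inscribed in the droplet interior with
#' non-overlapping `patch_size` x `patch_size` patches (so no background
#' pixels contaminate the texture statistics), computes GLCM features per
#' patch, and returns their arithmetic mean -- the droplet's feature point in
#' the (dissimilarity, homogeneity) plane.
#'
#' @param cx,cy droplet center, 0-based pixel coordinates (x = column).
#' @param r droplet radius in pixels.
#' @param image the source image matrix.
#' @param params a [glcm_params()].
#' @return named numeric `c(dissimilarity, homogeneity, n_patches)`;
#'   `n_patches = 0` (features `NA`) when the droplet is too small to hold a
#'   single patch, in which case it must be excluded from clustering.
#' @export
droplet_feature_point <- function(cx, cy, r, image, params = glcm_params()) {
  half <- floor((r - 1) / sqrt(2))  # inscribed square of the interior
  side <- 2L * half + 1L
  n_tiles <- side %/% params$patch_size
  if (n_tiles < 1L) {
    return(c(dissimilarity = NA_real_, homogeneity = NA_real_, n_patches = 0))
  }
  r0 <- round(cy) + 1L - half
  c0 <- round(cx) + 1L - half
  feats <- matrix(0, nrow = n_tiles^2, ncol = 2)
  k <- 0L
  for (ti in seq_len(n_tiles)) {
    for (tj in seq_len(n_tiles)) {
      rr <- r0 + (ti - 1L) * params$patch_size
      cc <- c0 + (tj - 1L) * params$patch_size
      patch <- image[rr:(rr + params$patch_size - 1L),
                     cc:(cc + params$patch_size - 1L)]
      k <- k + 1L
      feats[k, ] <- glcm_features(patch, params)
    }
  }
  c(dissimilarity = mean(feats[, 1]), homogeneity = mean(feats[, 2]),
    n_patches = n_tiles^2)
}

#' Cluster droplet feature points into growth-positive and negative
#'
#' k-means with k = 2 on standardized (dissimilarity, homogeneity) feature
#' points. The cluster with the higher mean (raw) dissimilarity is labeled
#' `positive`: a grown microcolony makes the droplet interior granular, which
#' raises dissimilarity, so the naming rule is invariant to k-means' internal
#' cluster indexing. If all feature points are identical there is no growth
#' signal to separate; every droplet is labeled `negative` with a warning.
#'
#' @param features matrix or data.frame with columns `dissimilarity` and
#'   `homogeneity` (one row per droplet, no missing values).
#' @param seed integer seed making the clustering deterministic.
#' @return factor of labels (`"negative"`/`"positive"`), one per row.
#' @export
classify_droplets <- function(features, seed = 1L) {
  X <- as.matrix(as.data.frame(features)[, c("dissimilarity", "homogeneity")])
  if (anyNA(X)) stop("feature points contain NA; exclude flagged droplets first")
  if (nrow(X) < 2L) stop("need at least 2 droplets to cluster")
  if (all(apply(X, 2, function(v) diff(range(v)) == 0))) {
    warning("all feature points identical: no growth signal, ",
            "labeling every droplet negative")
    return(factor(rep("negative", nrow(X)),
                  levels = c("negative", "positive")))
  }
  Z <- apply(X, 2, function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  })
  km <- withr::with_seed(seed, stats::kmeans(Z, centers = 2L, nstart = 10L))
  mean_diss <- tapply(X[, "dissimilarity"], km$cluster, mean)
  positive_cluster <- as.integer(names(which.max(mean_diss)))
  factor(ifelse(km$cluster == positive_cluster, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Attach ground-truth occupancy to detections
#'
#' Matches each detected droplet to the nearest manifest droplet in the same
#' image; a match farther than the detection's radius leaves the truth `NA`.
#'
#' @param detections data.frame with `image`, `cx`, `cy`, `r`.
#' @param manifest ground-truth manifest (columns `image`, `cx`, `cy`,
#'   `occupied`).
#' @return `detections` with a logical `truth` column appended.
#' @export
match_truth <- function(detections, manifest) {
  truth <- rep(NA, nrow(detections))
  for (i in seq_len(nrow(detections))) {
    m <- manifest[manifest$image == detections$image[i], ]
    if (nrow(m) == 0L) next
    d <- sqrt((m$cx - detections$cx[i])^2 + (m$cy - detections$cy[i])^2)
    j <- which.min(d)
    if (d[j] <= detections$r[i]) truth[i] <- m$occupied[j]
  }
  detections$truth <- truth
  detections
}

#' Evaluate droplet classification against ground truth
#'
#' Counts false negatives (occupied droplets labeled negative) and false
#' positives (empty droplets labeled positive). Rates are expressed relative
#' to the number of detected-positive droplets by default (the convention of
#' the fluorescence-validation benchmark this mirrors); `denominator =
#' "all"` uses the total droplet count instead.
#'
#' @param records data.frame with a `label` column
#'   (`"positive"`/`"negative"`) and a logical `truth` column; optionally an
#'   `image` column. Missing truth values are an error.
#' @param denominator denominator for the FN/FP rates.
#' @return a `confusion_summary` list: `n_images`, `n_droplets`,
#'   `n_detected_positive`, `n_false_negative`, `n_false_positive`,
#'   `fn_rate`, `fp_rate`, `positive_fraction`.
#' @export
evaluate_classification <- function(records,
                                    denominator = c("detected_positive",
                                                    "all")) {
  denominator <- match.arg(denominator)
  if (anyNA(records$truth)) {
    bad <- which(is.na(records$truth))
    ids <- if ("droplet_id" %in% names(records)) {
      records$droplet_id[bad]
    } else bad
    stop("missing ground truth for droplet(s): ",
         paste(utils::head(ids, 20), collapse = ", "))
  }
  lab_pos <- records$label == "positive"
  n_pos <- sum(lab_pos)
  fn <- sum(records$truth & !lab_pos)
  fp <- sum(!records$truth & lab_pos)
  denom <- if (denominator == "detected_positive") n_pos else nrow(records)
  structure(list(
    n_images = if ("image" %in% names(records)) {
      length(unique(records$image))
    } else NA_integer_,
    n_droplets = nrow(records),
    n_detected_positive = n_pos,
    n_false_negative = fn,
    n_false_positive = fp,
    fn_rate = if (denom > 0) fn / denom else NA_real_,
    fp_rate = if (denom > 0) fp / denom else NA_real_,
    positive_fraction = n_pos / nrow(records)
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "Droplet classification: %d droplets%s, %d detected positive (%.1f%%)\n",
    x$n_droplets,
    if (!is.na(x$n_images)) sprintf(" in %d images", x$n_images) else "",
    x$n_detected_positive, 100 * x$positive_fraction))
  cat(sprintf("  false negatives: %d (%.2f%%)   false positives: %d (%.2f%%)\n",
              x$n_false_negative, 100 * x$fn_rate,
              x$n_false_positive, 100 * x$fp_rate))
  invisible(x)
}

#' Detect, featurize and classify droplets across a set of images
#'
#' End-to-end image analysis: droplet detection, per-droplet GLCM feature
#' points, and k-means growth classification pooled over all images. When a
#' ground-truth manifest is supplied each record also carries its `truth`
#' flag for evaluation with [evaluate_classification()].
#'
#' @param images list of grayscale image matrices in [0, 1].
#' @param manifest optional ground-truth manifest.
#' @param params a [glcm_params()].
#' @param min_radius,max_radius detection radius band (pixels).
#' @param seed seed for the clustering step.
#' @return data.frame of droplet records: `image`, `droplet_id`, `cx`, `cy`,
#'   `r`, `dissimilarity`, `homogeneity`, `label` and (if a manifest was
#'   given) `truth`. Droplets too small to hold one analysis patch are
#'   excluded.
#' @export
classify_droplet_images <- function(images, manifest = NULL,
                                    params = glcm_params(),
                                    min_radius = 5, max_radius = Inf,
                                    seed = 1L) {
  recs <- lapply(seq_along(images), function(i) {
    det <- detect_droplets(images[[i]], min_radius, max_radius)
    if (nrow(det) == 0L) return(NULL)
    det$image <- i
    feats <- t(vapply(seq_len(nrow(det)), function(k) {
      droplet_feature_point(det$cx[k], det$cy[k], det$r[k], images[[i]],
                            params)
    }, numeric(3)))
    cbind(det, as.data.frame(feats))
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs) || nrow(recs) == 0L) {
    stop("no droplets detected in any image")
  }
  small <- recs$n_patches == 0
  if (any(small)) {
    recs <- recs[!small, , drop = FALSE]
  }
  recs$label <- classify_droplets(recs, seed = seed)
  recs$droplet_id <- seq_len(nrow(recs))
  if (!is.null(manifest)) recs <- match_truth(recs, manifest)
  rownames(recs) <- NULL
  recs[, c("image", "droplet_id", "cx", "cy", "r", "dissimilarity",
           "homogeneity", "n_patches", "label",
           if (!is.null(manifest)) "truth")]
}

#' Tally classified droplet records into counts
#'
#' Reduces one concentration's droplet records to the (N, N+) pair consumed
#' by the profile module, closing the images -> counts -> profile chain.
#'
#' @param records output of [classify_droplet_images()] for one
#'   concentration's droplet library.
#' @return named numeric `c(n_total, n_positive)`.
#' @export
tally_droplet_records <- function(records) {
  c(n_total = nrow(records), n_positive = sum(records$label == "positive"))
}
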