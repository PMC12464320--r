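#' GLCM texture-analysis parameters
#'
#' Hyperparameters of the grey-level co-occurrence matrix features used to
#' separate granular (grown) from smooth (empty) droplet interiors. Defaults:
#' 16 x 16 px patches, pixel offset distance 1, angles 0 and pi/2, 64 grey
#' levels, symmetric and normalized matrices -- standard texture-analysis
#' practice; all configurable.
#'
#' @param patch_size side of the square analysis patch in pixels; must be at
#'   least `2 * max(distances) + 1`.
#' @param distances integer pixel offsets (>= 1).
#' @param angles offset directions in radians (0 = horizontal neighbour,
#'   pi/2 = vertical).
#' @param n_levels number of grey quantization levels (>= 2); pixel values in
#'   [0, 1] are binned uniformly over the full range.
#' @param symmetric count each pair in both orders (matrix becomes
#'   symmetric).
#' @param normed normalize the matrix to sum to 1 (a joint probability
#'   distribution).
#' @return a `glcm_params` list.
#' @export
glcm_params <- function(patch_size = 16L, distances = 1L,
                        angles = c(0, pi / 2), n_levels = 64L,
                        symmetric = TRUE, normed = TRUE) {
  if (any(distances < 1)) stop("distances must be >= 1 pixel")
  if (patch_size < 2 * max(distances) + 1) {
    stop("patch_size must be at least 2 * max(distances) + 1")
  }
  if (n_levels < 2) stop("n_levels must be >= 2")
  structure(list(patch_size = as.integer(patch_size),
                 distances = as.integer(distances), angles = angles,
                 n_levels = as.integer(n_levels), symmetric = symmetric,
                 normed = normed),
            class = "glcm_params")
}

# uniform quantization of [0,1] grey values to 1..n_levels
quantize_grey <- function(x, n_levels) {
  if (any(x < 0 | x > 1)) stop("grey values must lie in [0, 1]")
  q <- floor(x * n_levels) + 1L
  q[q > n_levels] <- n_levels
  q
}

#' Grey-level co-occurrence matrix of a quantized patch
#'
#' Counts ordered pairs of grey levels `(i, j)` for pixels separated by the
#' offset `(distance, angle)`; with `symmetric = TRUE` each pair also counts
#' in reverse order, and with `normed = TRUE` the counts are divided by their
#' sum so the matrix is a joint probability distribution.
#'
#' @param q integer matrix of grey levels in `1..n_levels`.
#' @param n_levels number of grey levels.
#' @param distance pixel offset distance.
#' @param angle offset direction in radians.
#' @param symmetric,normed see [glcm_params()].
#' @return an `n_levels` x `n_levels` matrix.
#' @export
glcm_matrix <- function(q, n_levels, distance = 1L, angle = 0,
                        symmetric = TRUE, normed = TRUE) {
  dr <- as.integer(round(-distance * sin(angle)))
  dc <- as.integer(round(distance * cos(angle)))
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0L || length(c1) == 0L) {
    stop("patch too small for offset distance ", distance)
  }
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((as.vector(i) - 1L) * n_levels + as.vector(j),
                     nbins = n_levels * n_levels)
  P <- matrix(counts, nrow = n_levels, ncol = n_levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  if (normed) {
    s <- sum(P)
    if (s > 0) P <- P / s
  }
  P
}

#' GLCM texture features of an image patch
#'
#' Computes the two texture statistics used to classify droplet interiors,
#' averaged over the configured offsets:
#' dissimilarity \eqn{\sum_{i,j} P(i,j)\,|i-j|} (0 for a constant patch,
#' grows with grain) and homogeneity \eqn{\sum_{i,j} P(i,j)/(1+(i-j)^2)}
#' (1 iff all co-occurrence mass is on the diagonal).
#'
#' @param patch numeric matrix with grey values in [0, 1] (or an integer
#'   matrix of pre-quantized levels in `1..n_levels`).
#' @param params a [glcm_params()].
#' @return named numeric `c(dissimilarity, homogeneity)`.
#' @export
glcm_features <- function(patch, params = glcm_params()) {
  if (nrow(patch) < params$patch_size || ncol(patch) < params$patch_size) {
    stop("patch is ", nrow(patch), "x", ncol(patch),
         " but patch_size requires at least ",
         params$patch_size, "x", params$patch_size)
  }
  q <- if (is.integer(patch)) patch else quantize_grey(patch, params$n_levels)
  lev_diff <- abs(outer(seq_len(params$n_levels), seq_len(params$n_levels), "-"))
  diss <- hom <- 0
  combos <- expand.grid(distance = params$distances, angle = params$angles)
  for (k in seq_len(nrow(combos))) {
    P <- glcm_matrix(q, params$n_levels, combos$distance[k], combos$angle[k],
                     symmetric = params$symmetric, normed = params$normed)
    diss <- diss + sum(P * lev_diff)
    hom <- hom + sum(P / (1 + lev_diff^2))
  }
  c(dissimilarity = diss / nrow(combos), homogeneity = hom / nrow(combos))
}
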