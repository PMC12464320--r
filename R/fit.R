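#' Fit the Gompertz survival curve to a resistance profile
#'
#' Least-squares fit of \eqn{\phi(c) = \exp\{-(c/p_1)^{p_2}\}} to the
#' normalized proliferating fractions `F_R(c)`, by Levenberg-Marquardt
#' (minpack.lm) with multi-start initialization: the starting scale is the
#' concentration whose `F_R` is nearest 0.5 (fallback: the median tested
#' concentration) and the starting shape runs over 1, 2, 4, 8; the start with
#' the lowest residual sum of squares wins, ties broken towards the smaller
#' shape. The `c = 0` point (`F_R = 1`) is included; the fit is unweighted by
#' default, with optional weights (e.g. inverse replicate variance).
#'
#' A profile that never falls below 0.5 constrains the scale only weakly and
#' triggers a warning; a profile with no decline at all (all `F_R` within
#' noise of 1) is an error, since any fitted parameters would be arbitrary.
#' A fitted scale beyond the tested range is flagged with a warning but
#' returned (this is the heavy-tail regime where threshold concentrations
#' become not-determinable).
#'
#' @param profile a [resistance_profile()] or data.frame with columns
#'   `concentration` and `F_R` (>= 3 concentrations).
#' @param weights optional non-negative weights, one per concentration.
#' @return a `gompertz_fit` list: `p1`, `p2`, `rss`, `converged`,
#'   `c_max_tested`, `n_points`, `unit`, `fitted`, `data`.
#' @export
fit_gompertz <- function(profile, weights = NULL) {
  conc <- profile$concentration
  fr <- profile$F_R
  if (length(conc) < 3L) stop("need at least 3 concentrations to fit")
  if (is.null(weights)) weights <- rep(1, length(conc))
  if (length(weights) != length(conc) || any(weights < 0)) {
    stop("weights must be non-negative, one per concentration")
  }
  if (min(fr) > 0.95) {
    stop("no decline in the profile (all F_R > 0.95): the survival curve ",
         "is unidentified on this concentration range")
  }
  if (min(fr) > 0.5) {
    warning("profile never drops below 0.5; the fitted scale is only ",
            "weakly constrained by the tested range")
  }
  pos <- conc > 0
  i_half <- which.min(abs(fr - 0.5))
  p1_start <- if (conc[i_half] > 0) conc[i_half] else stats::median(conc[pos])

  df <- data.frame(conc = conc, fr = fr)
  best <- NULL
  for (p2_start in c(1, 2, 4, 8)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fr ~ exp(-(conc / p1)^p2), data = df,
        start = list(p1 = p1_start, p2 = p2_start),
        lower = c(p1 = 1e-9, p2 = 1e-9),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(weights * stats::residuals(fit)^2)
    cand <- list(fit = fit, rss = rss,
                 p2 = stats::coef(fit)[["p2"]])
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && cand$p2 < best$p2)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("Gompertz fit failed to converge from any start ",
         "(starts: p1 = ", signif(p1_start, 4), ", p2 in {1, 2, 4, 8})")
  }
  cf <- stats::coef(best$fit)
  c_max <- max(conc)
  if (cf[["p1"]] > c_max) {
    warning("fitted scale p1 = ", signif(cf[["p1"]], 4),
            " lies beyond the highest tested concentration ", c_max,
            "; interpret threshold concentrations with caution")
  }
  structure(list(
    p1 = cf[["p1"]], p2 = cf[["p2"]],
    rss = best$rss,
    converged = isTRUE(best$fit$convInfo$isConv),
    c_max_tested = c_max,
    n_points = length(conc),
    unit = attr(profile, "unit") %||% NA_character_,
    fitted = gompertz_survival(conc, cf[["p1"]], cf[["p2"]]),
    data = df
  ), class = "gompertz_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz survival fit: phi(c) = exp{-(c/p1)^p2}\n")
  cat(sprintf("  p1 (scale) = %.4g%s   p2 (shape) = %.4g\n",
              x$p1, if (!is.na(x$unit)) paste0(" ", x$unit) else "", x$p2))
  cat(sprintf("  RSS = %.4g over %d points (c_max = %g), converged: %s\n",
              x$rss, x$n_points, x$c_max_tested, x$converged))
  invisible(x)
}
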