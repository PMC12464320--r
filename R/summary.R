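#' Threshold policy for the iMIC concentration suite
#'
#' Survival levels defining the threshold concentrations read off the fitted
#' curve. `eps_total = 0.05` is fixed by definition (the concentration
#' inhibiting growth in more than 95% of droplets). The curve only reaches 0
#' asymptotically, so "first drop" and "complete inhibition" require
#' conventions: `eps_start = 0.99` (survival has dropped by 1%) and
#' `eps_all = 0.001` (99.9% inhibition) are the package defaults, both
#' exposed as policy rather than hard-coded. The near-complete-inhibition
#' concentration is reported as not determinable (ND) when it falls beyond
#' the highest tested concentration, in which case the experimentally
#' observed complete-inhibition concentration stands in for it in the degree
#' of heteroresistance.
#'
#' @param eps_start survival level defining the onset-of-inhibition
#'   concentration.
#' @param eps_total survival level for >95% inhibition.
#' @param eps_all survival level treated as complete inhibition.
#' @return a `threshold_policy` list.
#' @export
threshold_policy <- function(eps_start = 0.99, eps_total = 0.05,
                             eps_all = 0.001) {
  if (!(0 < eps_all && eps_all < eps_total && eps_total < eps_start &&
        eps_start < 1)) {
    stop("need 0 < eps_all < eps_total < eps_start < 1")
  }
  structure(list(eps_start = eps_start, eps_total = eps_total,
                 eps_all = eps_all),
            class = "threshold_policy")
}

#' Experimentally observed complete-inhibition concentration
#'
#' The smallest tested concentration at which no replicate shows a single
#' positive droplet, at that concentration and at every higher one (a fluke
#' zero below a concentration that still shows growth does not qualify).
#' This is the droplet analogue of a classical MIC reading and substitutes
#' for the fitted complete-inhibition concentration when the latter is not
#' determinable from the tested range.
#'
#' @param tables list of [count_table] replicates on a common grid.
#' @return concentration, or `NA` with attribute `status = "not_reached"`
#'   when growth persists up to the highest tested concentration.
#' @export
imic_exp <- function(tables) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  grid <- sort(tables[[1]]$concentration)
  pos <- sapply(tables, function(t) t$n_positive[order(t$concentration)])
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = length(tables))
  any_growth <- rowSums(pos) > 0
  # smallest c such that no growth at c and everywhere above
  clear_above <- rev(cumsum(rev(any_growth))) == 0
  clear_above[grid == 0] <- FALSE
  if (!any(clear_above)) {
    return(structure(NA_real_, status = "not_reached"))
  }
  structure(min(grid[clear_above]), status = "ok")
}

#' Degree of heteroresistance
#'
#' Ratio of the complete-inhibition concentration to the
#' onset-of-inhibition concentration, a width measure of the individual-MIC
#' distribution on the concentration axis: the larger the ratio, the more
#' diverse the single-cell susceptibilities.
#'
#' @param imic_all complete-inhibition concentration (fitted, or the
#'   experimental stand-in when the fitted one is not determinable).
#' @param imic_start onset-of-inhibition concentration (> 0).
#' @return the ratio.
#' @export
degree_of_heteroresistance <- function(imic_all, imic_start) {
  if (is.na(imic_all) || is.na(imic_start)) return(NA_real_)
  if (imic_start <= 0) {
    stop("imic_start must be positive for a defined degree of heteroresistance")
  }
  imic_all / imic_start
}

#' Full iMIC statistic suite for a fitted sample
#'
#' Populates, from a converged Gompertz fit, every statistic of the
#' single-sample summary: distribution mode, closed-form mean/SD/skewness/
#' kurtosis (with quadrature-based numerical error estimates), RMSD
#' (SD / mode), coefficient of variation (SD / mean), the threshold
#' concentrations at the policy's survival levels, the experimentally
#' observed complete-inhibition concentration (when raw replicate tables are
#' supplied), and the degree of heteroresistance. When the fitted
#' complete-inhibition concentration lies beyond the tested range (status
#' ND), the experimental value substitutes for it in the DoH; if neither is
#' available the DoH is `NA` with an explanatory status. A degenerate shape
#' (`p2 <= 1`, mode at the origin) leaves mode-based statistics undefined
#' with explicit statuses rather than dividing by zero.
#'
#' @param fit a [fit_gompertz()] result.
#' @param policy a [threshold_policy()].
#' @param tables optional raw replicate [count_table]s for the experimental
#'   complete-inhibition concentration.
#' @return an `imic_summary` list.
#' @export
imic_summary <- function(fit, policy = threshold_policy(), tables = NULL) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!isTRUE(fit$converged)) {
    warning("summarizing a fit that did not report convergence")
  }
  p1 <- fit$p1; p2 <- fit$p2
  mode <- suppressWarnings(imic_mode(p1, p2))
  mom <- closed_form_moments(p1, p2)
  start <- solve_threshold(p1, p2, policy$eps_start)
  total <- solve_threshold(p1, p2, policy$eps_total)
  all_c <- solve_threshold(p1, p2, policy$eps_all, c_max = fit$c_max_tested)
  exp_c <- if (!is.null(tables)) imic_exp(tables) else {
    structure(NA_real_, status = "unavailable")
  }

  all_nd <- identical(attr(all_c, "status"), "ND")
  doh_source <- if (!all_nd) "fitted" else if (!is.na(exp_c)) {
    "experimental"
  } else "undefined"
  inhibit_all <- if (!all_nd) as.numeric(all_c) else as.numeric(exp_c)
  doh_status <- "ok"
  doh <- if (mode <= 0 || as.numeric(start) <= 0) {
    doh_status <- "undefined: onset concentration degenerates to 0"
    NA_real_
  } else if (doh_source == "undefined") {
    doh_status <- "undefined: complete inhibition not determinable nor observed"
    NA_real_
  } else {
    degree_of_heteroresistance(inhibit_all, as.numeric(start))
  }

  structure(list(
    p1 = p1, p2 = p2, unit = fit$unit,
    imic_mode = mode,
    imic_mean = mom$mean,
    imic_sd = mom$sd,
    imic_skewness = mom$skewness,
    imic_kurtosis = mom$kurtosis,
    numerical_error = mom$numerical_error,
    rmsd = if (mode > 0) mom$sd / mode else NA_real_,
    cov = mom$sd / mom$mean,
    imic_start = as.numeric(start),
    imic_total = as.numeric(total),
    imic_all = as.numeric(all_c),
    imic_all_status = attr(all_c, "status"),
    imic_exp = as.numeric(exp_c),
    imic_exp_status = attr(exp_c, "status"),
    doh = doh, doh_source = doh_source, doh_status = doh_status
  ), class = "imic_summary")
}

#' @export
print.imic_summary <- function(x, ...) {
  u <- if (!is.na(x$unit)) paste0(" ", x$unit) else ""
  cat("Individual-MIC summary (Gompertz fit: p1 =", signif(x$p1, 4),
      " p2 =", signif(x$p2, 4), ")\n")
  fmt <- function(v) if (is.na(v)) "ND" else signif(v, 4)
  cat(sprintf("  mode %s%s   mean %s%s   SD %s%s\n",
              fmt(x$imic_mode), u, fmt(x$imic_mean), u, fmt(x$imic_sd), u))
  cat(sprintf("  RMSD %s   CoV %s   skewness %s   kurtosis %s\n",
              fmt(x$rmsd), fmt(x$cov), fmt(x$imic_skewness),
              fmt(x$imic_kurtosis)))
  cat(sprintf("  start %s%s   total %s%s   all %s%s   exp %s%s\n",
              fmt(x$imic_start), u, fmt(x$imic_total), u,
              fmt(x$imic_all), u, fmt(x$imic_exp), u))
  cat(sprintf("  DoH %s (from %s)\n", fmt(x$doh), x$doh_source))
  invisible(x)
}

#' @export
as.data.frame.imic_summary <- function(x, ...) {
  data.frame(
    statistic = c("imic_mode", "imic_mean", "sd", "rmsd", "cov",
                  "imic_start", "imic_total", "imic_all", "imic_exp",
                  "doh", "kurtosis", "skewness"),
    value = c(x$imic_mode, x$imic_mean, x$imic_sd, x$rmsd, x$cov,
              x$imic_start, x$imic_total, x$imic_all, x$imic_exp,
              x$doh, x$imic_kurtosis, x$imic_skewness)
  )
}
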