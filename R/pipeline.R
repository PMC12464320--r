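#' Run the full single-cell AST analysis over an experiment
#'
#' Orchestrates counts -> profile -> Gompertz fit -> iMIC summary for every
#' sample of an experiment, compares each sample's fitted curve to a
#' designated control, and collects degree-of-heteroresistance fold changes.
#' Each sample is either a list of replicate [count_table]s (field `tables`)
#' or a [simulation_config()] (field `sim_config`) that is simulated on the
#' fly; image-derived counts enter through [classify_droplet_images()] +
#' [tally_droplet_records()] upstream. A failure in one sample is recorded
#' in that sample's `error` field and does not abort the others.
#'
#' @param samples named list; each element a list with `tables` or
#'   `sim_config`, and optionally `unit`.
#' @param control name of the control (unexposed) sample, or `NULL` for no
#'   comparisons.
#' @param policy a [threshold_policy()].
#' @param seed integer seed applied to per-sample simulation (offset per
#'   sample for independence) and carried in the metadata.
#' @return an `experiment_report`: per-sample results (`profile`, `fit`,
#'   `summary`, `p_value`), DoH `fold_changes`, and `metadata`.
#' @export
run_pipeline <- function(samples, control = NULL,
                         policy = threshold_policy(), seed = 1L) {
  stopifnot(is.list(samples), !is.null(names(samples)),
            !anyDuplicated(names(samples)))
  if (!is.null(control) && !control %in% names(samples)) {
    stop("control sample '", control, "' not found among samples")
  }
  results <- vector("list", length(samples))
  names(results) <- names(samples)
  for (i in seq_along(samples)) {
    nm <- names(samples)[i]
    res <- tryCatch({
      s <- samples[[i]]
      tables <- if (!is.null(s$tables)) {
        s$tables
      } else if (!is.null(s$sim_config)) {
        cfg <- s$sim_config
        cfg$seed <- (s$sim_config$seed %||% seed) + i
        simulate_counts(cfg)
      } else {
        stop("sample '", nm, "' has neither `tables` nor `sim_config`")
      }
      profile <- resistance_profile(tables, unit = s$unit %||% NA_character_)
      fit <- fit_gompertz(profile)
      summary <- imic_summary(fit, policy, tables)
      message(sprintf("[pipeline] sample=%s n_conc=%d n_rep=%d p1=%.4g p2=%.4g",
                      nm, nrow(profile), length(tables), fit$p1, fit$p2))
      list(name = nm, tables = tables, profile = profile, fit = fit,
           summary = summary, p_value = NA_real_, error = NULL)
    }, error = function(e) {
      warning("sample '", nm, "' failed: ", conditionMessage(e))
      list(name = nm, error = conditionMessage(e))
    })
    results[[i]] <- res
  }
  if (!is.null(control) && is.null(results[[control]]$error)) {
    ctrl_fit <- results[[control]]$fit
    for (nm in setdiff(names(results), control)) {
      if (!is.null(results[[nm]]$error)) next
      results[[nm]]$p_value <-
        compare_to_control(results[[nm]]$fit, ctrl_fit)
    }
  }
  report <- structure(list(
    samples = results,
    control = control,
    fold_changes = NULL,
    metadata = list(seed = seed, policy = policy,
                    version = as.character(utils::packageVersion("dropletAST")))
  ), class = "experiment_report")
  report$fold_changes <- fold_change_doh(report)
  report
}

#' Compare a sample's fitted curve to the control's
#'
#' Paired two-sided t-test on the two fitted survival curves evaluated on a
#' shared grid of `n_grid` points spanning `[0, c_max]` (the smaller of the
#' two tested ranges). This is a documented convention for curve-level
#' comparison, not an attempt to reproduce any particular published test
#' statistic. `method = "replicates"` instead refits each replicate
#' separately in both samples and applies Welch's t-test to the per-replicate
#' fitted scales. Identical curves give `p = 1` by convention (flagged with
#' a warning).
#'
#' @param fit,control_fit [fit_gompertz()] results (for
#'   `method = "replicates"`, pass the samples' replicate tables via
#'   `tables` and `control_tables`).
#' @param n_grid number of evaluation points.
#' @param method `"curve"` (default) or `"replicates"`.
#' @param tables,control_tables replicate [count_table]s, only for
#'   `method = "replicates"`.
#' @return p-value in [0, 1].
#' @export
compare_to_control <- function(fit, control_fit, n_grid = 50L,
                               method = c("curve", "replicates"),
                               tables = NULL, control_tables = NULL) {
  method <- match.arg(method)
  if (method == "replicates") {
    if (is.null(tables) || is.null(control_tables)) {
      stop("method = 'replicates' needs `tables` and `control_tables`")
    }
    p1s <- vapply(tables, function(t) {
      fit_gompertz(resistance_profile(list(t)))$p1
    }, numeric(1))
    p1c <- vapply(control_tables, function(t) {
      fit_gompertz(resistance_profile(list(t)))$p1
    }, numeric(1))
    return(stats::t.test(p1s, p1c)$p.value)
  }
  c_max <- min(fit$c_max_tested, control_fit$c_max_tested)
  grid <- seq(0, c_max, length.out = n_grid)
  a <- gompertz_survival(grid, fit$p1, fit$p2)
  b <- gompertz_survival(grid, control_fit$p1, control_fit$p2)
  d <- a - b
  if (max(abs(d)) < 1e-12 || stats::sd(d) < 1e-14) {
    warning("fitted curves are (numerically) identical; p = 1 by convention")
    return(1)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Degree-of-heteroresistance fold changes versus the control
#'
#' Ratio of each sample's DoH to the control's. Defined only when both DoH
#' values exist; otherwise `NA` (all `NA` when the control's DoH is
#' undefined).
#'
#' @param report an `experiment_report` from [run_pipeline()].
#' @return named numeric vector of fold changes (control excluded).
#' @export
fold_change_doh <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  if (is.null(report$control)) return(NULL)
  ctrl <- report$samples[[report$control]]
  ctrl_doh <- if (is.null(ctrl$error)) ctrl$summary$doh else NA_real_
  others <- setdiff(names(report$samples), report$control)
  out <- vapply(others, function(nm) {
    s <- report$samples[[nm]]
    if (!is.null(s$error) || is.na(ctrl_doh) || ctrl_doh <= 0) {
      return(NA_real_)
    }
    s_doh <- s$summary$doh
    if (is.na(s_doh)) NA_real_ else s_doh / ctrl_doh
  }, numeric(1))
  out
}

#' Experiment report as a statistics-by-samples table
#'
#' Rows are the iMIC statistics, columns the samples -- the layout of a
#' multi-sample heteroresistance summary table, ready for CSV export.
#'
#' @param report an `experiment_report`.
#' @return data.frame with a `statistic` column plus one column per sample.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  ok <- Filter(function(s) is.null(s$error), report$samples)
  if (length(ok) == 0L) stop("no sample produced a summary")
  cols <- lapply(ok, function(s) as.data.frame(s$summary)$value)
  out <- data.frame(statistic = as.data.frame(ok[[1]]$summary)$statistic)
  for (nm in names(ok)) out[[nm]] <- cols[[nm]]
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Single-cell AST experiment report:", length(x$samples), "sample(s)")
  if (!is.null(x$control)) cat(", control =", x$control)
  cat("\n")
  for (s in x$samples) {
    if (!is.null(s$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", s$name, s$error))
    } else {
      cat(sprintf("  %s: p1=%.4g p2=%.4g DoH=%s%s\n", s$name,
                  s$fit$p1, s$fit$p2,
                  if (is.na(s$summary$doh)) "ND" else signif(s$summary$doh, 4),
                  if (!is.na(s$p_value)) {
                    sprintf(" (p vs control = %.3g)", s$p_value)
                  } else ""))
    }
  }
  if (!is.null(x$fold_changes)) {
    cat("  DoH fold changes vs control:\n")
    for (nm in names(x$fold_changes)) {
      cat(sprintf("    %s: %s\n", nm,
                  if (is.na(x$fold_changes[nm])) "ND" else
                    signif(x$fold_changes[nm], 4)))
    }
  }
  invisible(x)
}
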