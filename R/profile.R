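#' Per-replicate droplet count table
#'
#' One biological replicate of a single-cell AST run: for each antibiotic
#' concentration on the grid, the total number of screened droplets `N(c)`
#' and the number showing detectable bacterial growth (positive droplets)
#' `N+(c)`.
#'
#' @param concentration numeric, unique, must include 0 (the antibiotic-free
#'   control library); any order, stored sorted ascending.
#' @param n_total droplets screened per concentration.
#' @param n_positive positive droplets per concentration; `0 <= n_positive <=
#'   n_total`.
#' @param replicate_id identifier of the biological replicate.
#' @return a `count_table` (data.frame with columns `replicate`,
#'   `concentration`, `n_total`, `n_positive`).
#' @export
count_table <- function(concentration, n_total, n_positive,
                        replicate_id = "rep1") {
  stopifnot(length(concentration) == length(n_total),
            length(concentration) == length(n_positive))
  if (anyDuplicated(concentration)) {
    stop("concentrations must be unique within a replicate")
  }
  if (!any(concentration == 0)) {
    stop("the concentration grid must include c = 0 (no-antibiotic control)")
  }
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  if (any(n_positive < 0) || any(n_positive > n_total)) {
    stop("need 0 <= n_positive <= n_total at every concentration")
  }
  ord <- order(concentration)
  out <- data.frame(
    replicate = as.character(replicate_id),
    concentration = concentration[ord],
    n_total = n_total[ord],
    n_positive = n_positive[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("count_table", "data.frame")
  out
}

#' Read and write droplet count tables as TSV
#'
#' The on-disk schema has one row per (replicate, concentration) with columns
#' `replicate`, `concentration`, `n_total`, `n_positive` and a header row.
#' Concentrations are in the sample's native unit; no conversion is applied.
#'
#' @param path TSV file path.
#' @return `read_count_tables`: a list of [count_table], one per replicate.
#' @export
read_count_tables <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("replicate", "concentration", "n_total", "n_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("count table TSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  lapply(split(df, df$replicate), function(d) {
    count_table(d$concentration, d$n_total, d$n_positive, d$replicate[1])
  })
}

#' @rdname read_count_tables
#' @param tables a [count_table] or list of them.
#' @export
write_count_tables <- function(tables, path) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positive droplet fraction per concentration
#'
#' `f+(c) = N+(c) / N(c)` for each row of a count table.
#'
#' @param table a [count_table].
#' @return data.frame with columns `concentration`, `f_plus`.
#' @export
positive_fraction <- function(table) {
  if (any(table$n_total == 0)) {
    bad <- table$concentration[table$n_total == 0]
    stop("n_total = 0 at concentration(s): ", paste(bad, collapse = ", "))
  }
  data.frame(concentration = table$concentration,
             f_plus = table$n_positive / table$n_total)
}

#' Normalize positive fractions to the antibiotic-free control
#'
#' `F_R(c) = f+(c) / f+(0)`: the fraction of individually encapsulated cells
#' that proliferate at concentration `c`, relative to the no-antibiotic
#' library. Values above 1 (sampling noise) are preserved, not clipped, since
#' they are legitimate fit input.
#'
#' @param f_plus data.frame from [positive_fraction()].
#' @return the same data.frame with an `F_R` column appended.
#' @export
normalize_fraction <- function(f_plus) {
  i0 <- which(f_plus$concentration == 0)
  if (length(i0) != 1L) stop("profile must contain exactly one c = 0 row")
  f0 <- f_plus$f_plus[i0]
  if (f0 <= 0) {
    stop("f+(0) = 0: no growth in the antibiotic-free control, ",
         "normalized profile is undefined")
  }
  f_plus$F_R <- f_plus$f_plus / f0
  f_plus
}

#' Average raw droplet counts across biological replicates
#'
#' Per concentration, the mean of `N(c)` and of `N+(c)` across replicates
#' (the counts are averaged before the fraction is formed, so the fitted
#' profile is driven by the pooled evidence). All replicates must share the
#' same concentration grid.
#'
#' @param tables list of [count_table] on a common grid.
#' @return a [count_table] with `replicate = "average"` (counts may be
#'   non-integer).
#' @export
average_replicates <- function(tables) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  grids <- lapply(tables, function(t) t$concentration)
  ref <- grids[[1]]
  for (i in seq_along(grids)) {
    if (!isTRUE(all.equal(sort(grids[[i]]), sort(ref)))) {
      missing_c <- c(setdiff(ref, grids[[i]]), setdiff(grids[[i]], ref))
      stop("replicate ", i, " is on a different concentration grid ",
           "(mismatched concentrations: ",
           paste(unique(missing_c), collapse = ", "), ")")
    }
  }
  n_tot <- rowMeans(sapply(tables, function(t) t$n_total[order(t$concentration)]))
  n_pos <- rowMeans(sapply(tables, function(t) t$n_positive[order(t$concentration)]))
  count_table(sort(ref), n_tot, n_pos, replicate_id = "average")
}

#' Build the normalized resistance profile from replicate counts
#'
#' Composes [positive_fraction()], [average_replicates()] and
#' [normalize_fraction()] into the dose-response profile used for fitting.
#' By default raw counts are averaged across replicates first and the pooled
#' fractions normalized (`order = "average_first"`); the alternative
#' (`"normalize_first"`: normalize each replicate by its own control, then
#' average the profiles) is provided for sensitivity analysis. Per-point
#' standard deviations of the replicate-level `F_R` are always retained for
#' error bars / optional fit weighting.
#'
#' @param tables list of [count_table] (or a single one).
#' @param order averaging order, see above.
#' @param unit concentration unit tag carried as metadata (e.g. "ng/mL").
#' @return a `resistance_profile`: data.frame with columns `concentration`,
#'   `f_plus`, `F_R`, `sd`, plus attributes `n_replicates` and `unit`.
#' @export
resistance_profile <- function(tables,
                               order = c("average_first", "normalize_first"),
                               unit = NA_character_) {
  order <- match.arg(order)
  if (inherits(tables, "count_table")) tables <- list(tables)
  per_rep <- lapply(tables, function(t) normalize_fraction(positive_fraction(t)))
  fr_mat <- sapply(per_rep, function(p) p$F_R[order(p$concentration)])
  if (is.null(dim(fr_mat))) fr_mat <- matrix(fr_mat, ncol = length(per_rep))
  sd_fr <- if (ncol(fr_mat) > 1) apply(fr_mat, 1, stats::sd) else rep(0, nrow(fr_mat))

  avg <- average_replicates(tables)
  fp <- positive_fraction(avg)
  prof <- if (order == "average_first") {
    normalize_fraction(fp)
  } else {
    data.frame(concentration = fp$concentration, f_plus = fp$f_plus,
               F_R = rowMeans(fr_mat))
  }
  prof$sd <- sd_fr
  structure(prof,
            n_replicates = length(tables),
            unit = unit,
            class = c("resistance_profile", "data.frame"))
}

#' @export
print.resistance_profile <- function(x, ...) {
  cat("Resistance profile:", nrow(x), "concentrations,",
      attr(x, "n_replicates"), "replicate(s)")
  if (!is.na(attr(x, "unit"))) cat(" [", attr(x, "unit"), "]", sep = "")
  cat("\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Write a resistance profile as TSV
#'
#' Columns `concentration`, `f_plus`, `F_R`, `sd`, for plotting or external
#' fitting.
#'
#' @param profile a `resistance_profile`.
#' @param path output TSV path.
#' @export
write_resistance_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
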