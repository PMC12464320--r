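#' Configuration for a synthetic single-cell AST experiment
#'
#' Defines the ground truth and sampling design of a simulated droplet
#' experiment. Per-cell individual MICs are drawn from a Weibull distribution
#' with scale `true_p1` and shape `true_p2` -- the distribution whose survival
#' function is the Gompertz dose-response curve fitted downstream, so the
#' generator and the model are exactly matched by construction. Droplet
#' occupancy is Poisson with \eqn{\lambda =} `cfu_per_ml` \eqn{\times} droplet
#' volume (in mL), emulating stochastic confinement.
#'
#' Defaults reproduce the reference study design: scale 9.8, shape 4.4 (an
#' unexposed ciprofloxacin-type sample, concentrations in ng/mL), a
#' fine-grained concentration ladder around the scale, 5000 droplets per
#' concentration, \eqn{\lambda = 0.1} (1e5 CFU/mL in 1 nL droplets) and three
#' biological replicates.
#'
#' @param true_p1 ground-truth Weibull scale (concentration units, > 0).
#' @param true_p2 ground-truth Weibull shape (> 0).
#' @param conc_grid concentration grid, ascending, first element 0.
#' @param n_droplets_per_conc droplets screened per concentration (>= 1).
#' @param cfu_per_ml inoculum density (cells/mL, > 0).
#' @param droplet_volume_nl droplet volume in nanolitres (> 0).
#' @param n_replicates number of biological replicates.
#' @param multi_occupancy_rule `"single_only"` (default): an occupied droplet
#'   grows iff a single cell's iMIC exceeds the concentration, the one-cell
#'   assumption of the analysis framework; `"max_of_k"`: a droplet with k
#'   cells grows iff the maximum of its k per-cell iMIC values exceeds the
#'   concentration (probes the bias from rare multiple encapsulation).
#' @param seed integer seed for reproducibility (`NULL`: use current RNG
#'   state).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(true_p1 = 9.8,
                              true_p2 = 4.4,
                              conc_grid = c(0, 2, 4, 6, 8, 9, 10, 11, 12,
                                            13, 14, 16, 18, 20),
                              n_droplets_per_conc = 5000L,
                              cfu_per_ml = 1e5,
                              droplet_volume_nl = 1,
                              n_replicates = 3L,
                              multi_occupancy_rule = c("single_only",
                                                       "max_of_k"),
                              seed = NULL) {
  multi_occupancy_rule <- match.arg(multi_occupancy_rule)
  if (true_p1 <= 0) stop("true_p1 must be > 0")
  if (true_p2 <= 0) stop("true_p2 must be > 0")
  if (is.unsorted(conc_grid, strictly = TRUE) || conc_grid[1] != 0) {
    stop("conc_grid must be strictly ascending and start at 0")
  }
  if (n_droplets_per_conc < 1) stop("n_droplets_per_conc must be >= 1")
  if (cfu_per_ml <= 0) stop("cfu_per_ml must be > 0")
  if (droplet_volume_nl <= 0) stop("droplet_volume_nl must be > 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(
    true_p1 = true_p1, true_p2 = true_p2, conc_grid = conc_grid,
    n_droplets_per_conc = as.integer(n_droplets_per_conc),
    cfu_per_ml = cfu_per_ml, droplet_volume_nl = droplet_volume_nl,
    n_replicates = as.integer(n_replicates),
    multi_occupancy_rule = multi_occupancy_rule, seed = seed
  ), class = "simulation_config")
}

#' Poisson droplet occupancy distribution
#'
#' Probability that a droplet encapsulates zero, one, or two-or-more cells
#' under stochastic confinement, with mean occupancy
#' \eqn{\lambda = } `cfu_per_ml` \eqn{\times} droplet volume in mL. At the
#' standard design point (1e5 CFU/mL, 1 nL droplets; \eqn{\lambda = 0.1})
#' roughly 90% of droplets are empty and 9% contain a single bacterium, so
#' single-cell encapsulation dominates among occupied droplets.
#'
#' @param cfu_per_ml inoculum density in CFU/mL (> 0).
#' @param droplet_volume_nl droplet volume in nanolitres (> 0).
#' @return named numeric `c(p_empty, p_single, p_multi)` summing to 1
#'   exactly, with attribute `lambda`.
#' @examples
#' poisson_occupancy(1e5, 1)
#' @export
poisson_occupancy <- function(cfu_per_ml, droplet_volume_nl) {
  if (length(cfu_per_ml) != 1L || !is.finite(cfu_per_ml) || cfu_per_ml <= 0) {
    stop("`cfu_per_ml` must be a single positive number")
  }
  if (length(droplet_volume_nl) != 1L || !is.finite(droplet_volume_nl) ||
      droplet_volume_nl <= 0) {
    stop("`droplet_volume_nl` must be a single positive number")
  }
  lambda <- cfu_per_ml * droplet_volume_nl * 1e-6  # nL -> mL
  p0 <- stats::dpois(0, lambda)
  p1 <- stats::dpois(1, lambda)
  # complement computed off the rounded sum so the three masses add to 1
  # exactly in floating point
  structure(c(p_empty = p0, p_single = p1, p_multi = 1 - (p0 + p1)),
            lambda = lambda)
}

#' Simulate droplet count tables with known ground truth
#'
#' For each replicate and each concentration on the grid, draws droplet
#' occupancy counts from the Poisson design, draws a Weibull(scale
#' `true_p1`, shape `true_p2`) individual MIC for every encapsulated cell,
#' and scores a droplet positive when its governing iMIC exceeds the tested
#' concentration (strictly: growth at `c = 0` is certain for occupied
#' droplets). Under the `single_only` rule the expected normalized profile is
#' exactly \eqn{\exp\{-(c/p_1)^{p_2}\}}.
#'
#' @param config a [simulation_config()].
#' @return list of [count_table], one per replicate.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  run <- function() {
    occ <- poisson_occupancy(config$cfu_per_ml, config$droplet_volume_nl)
    lambda <- attr(occ, "lambda")
    n <- config$n_droplets_per_conc
    lapply(seq_len(config$n_replicates), function(r) {
      n_pos <- vapply(config$conc_grid, function(conc) {
        k <- stats::rpois(n, lambda)
        occupied <- which(k > 0)
        if (length(occupied) == 0L) return(0L)
        if (config$multi_occupancy_rule == "single_only") {
          imic <- stats::rweibull(length(occupied),
                                  shape = config$true_p2,
                                  scale = config$true_p1)
          sum(imic > conc)
        } else {
          kk <- k[occupied]
          cell_imic <- stats::rweibull(sum(kk),
                                       shape = config$true_p2,
                                       scale = config$true_p1)
          droplet <- rep.int(seq_along(occupied), kk)
          max_imic <- vapply(split(cell_imic, droplet), max, numeric(1))
          sum(max_imic > conc)
        }
      }, integer(1))
      count_table(config$conc_grid, rep(n, length(config$conc_grid)),
                  n_pos, replicate_id = paste0("rep", r))
    })
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}
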