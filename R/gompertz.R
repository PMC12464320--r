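#' Gompertz survival function for individual-MIC dose response
#'
#' Fraction of individually encapsulated cells still proliferating at
#' antibiotic concentration `conc`, under the two-parameter survival model
#' \deqn{\phi(c) = \exp\{-(c/p_1)^{p_2}\}.}
#' `p1` is the concentration at maximum slope of the dose-response curve and
#' `p2` the (dimensionless) slope parameter at `conc = p1`. The model is the
#' survival function of a Weibull distribution with scale `p1` and shape `p2`.
#'
#' @param conc numeric vector of antibiotic concentrations (>= 0), in the
#'   sample's native unit.
#' @param p1 scale parameter (> 0), same unit as `conc`.
#' @param p2 shape parameter (> 0), dimensionless.
#' @return numeric vector of survival fractions in (0, 1].
#' @examples
#' gompertz_survival(c(0, 10), p1 = 10, p2 = 4)
#' @export
gompertz_survival <- function(conc, p1, p2) {
  check_shape_scale(p1, p2)
  if (any(conc < 0)) stop("`conc` must be non-negative")
  exp(-(conc / p1)^p2)
}

#' Probability density of the individual-MIC distribution
#'
#' Density of per-cell minimum inhibitory concentrations, the negative first
#' derivative of the fitted survival curve:
#' \deqn{p(c) = \frac{p_2 c^{p_2-1}}{p_1^{p_2}} \exp\{-(c/p_1)^{p_2}\}.}
#'
#' @inheritParams gompertz_survival
#' @return numeric vector of densities (non-negative; integrates to 1).
#' @export
pdf_imic <- function(conc, p1, p2) {
  check_shape_scale(p1, p2)
  if (any(conc < 0)) stop("`conc` must be non-negative")
  out <- numeric(length(conc))
  pos <- conc > 0
  cp <- conc[pos]
  out[pos] <- exp(log(p2) + (p2 - 1) * log(cp) - p2 * log(p1) - (cp / p1)^p2)
  # c = 0 limit depends on the shape
  if (any(!pos)) {
    out[!pos] <- if (p2 > 1) 0 else if (p2 == 1) 1 / p1 else Inf
  }
  out
}

#' Mode of the individual-MIC distribution
#'
#' Inflection point of the survival curve (second derivative zero), i.e. the
#' most frequent iMIC value:
#' \deqn{c_{mode} = p_1 \{1 - 1/p_2\}^{1/p_2}.}
#' For `p2 <= 1` the density is monotone decreasing and the mode degenerates
#' to the origin; 0 is returned with a warning.
#'
#' @inheritParams gompertz_survival
#' @return mode concentration (same unit as `p1`).
#' @export
imic_mode <- function(p1, p2) {
  check_shape_scale(p1, p2)
  if (p2 <= 1) {
    if (p2 < 1) {
      warning("shape p2 < 1: density is monotone, mode degenerates to 0")
    }
    return(0)
  }
  p1 * (1 - 1 / p2)^(1 / p2)
}

# k-th raw moment E[c^k] = p1^k * Gamma(1 + k/p2), via log-gamma for stability
weibull_raw_moment <- function(p1, p2, k) {
  exp(k * log(p1) + lgamma(1 + k / p2))
}

#' Closed-form moments of the individual-MIC distribution
#'
#' Mean, standard deviation, skewness and (Pearson) kurtosis of the iMIC
#' density, from the gamma-function closed forms
#' \eqn{\mu = (p_1/p_2)\Gamma(1/p_2)},
#' \eqn{\sigma = \sqrt{(2p_1^2/p_2)\Gamma(2/p_2) - (p_1^2/p_2^2)\Gamma^2(1/p_2)}},
#' \eqn{\gamma = \mu_3/\sigma^3} and kurtosis from raw moments
#' \eqn{E[c^k] = p_1^k\,\Gamma(1 + k/p_2)}. Evaluated via log-gamma so extreme
#' shapes do not overflow.
#'
#' When `numerical_check = TRUE` the central moments are also computed by
#' adaptive quadrature of the density and the absolute differences are
#' returned as `numerical_error`, an error estimate for the skewness and
#' kurtosis values.
#'
#' @inheritParams gompertz_survival
#' @param numerical_check cross-check closed forms against quadrature.
#' @return list with `mean`, `sd`, `skewness`, `kurtosis`, and (optionally)
#'   `numerical_error` (named: skewness, kurtosis).
#' @export
closed_form_moments <- function(p1, p2, numerical_check = TRUE) {
  check_shape_scale(p1, p2)
  m1 <- weibull_raw_moment(p1, p2, 1)
  m2 <- weibull_raw_moment(p1, p2, 2)
  m3 <- weibull_raw_moment(p1, p2, 3)
  m4 <- weibull_raw_moment(p1, p2, 4)
  mu <- m1
  var <- m2 - m1^2
  sd <- sqrt(var)
  mu3 <- m3 - 3 * mu * var - mu^3
  skew <- mu3 / sd^3
  mu4 <- m4 - 4 * mu * m3 + 6 * mu^2 * m2 - 3 * mu^4
  kurt <- mu4 / var^2
  out <- list(mean = mu, sd = sd, skewness = skew, kurtosis = kurt)
  if (numerical_check) {
    num <- numerical_moments(p1, p2)
    out$numerical_error <- c(
      skewness = abs(skew - num["skewness"][[1]]),
      kurtosis = abs(kurt - num["kurtosis"][[1]])
    )
  }
  out
}

# moments by adaptive quadrature of the density (independent of closed
# forms); integration runs on the unit-scale density (substitution u = c/p1,
# exact) so the quadrature is well-conditioned for any concentration unit
numerical_moments <- function(p1, p2) {
  q <- function(f) {
    # unit-scale integrands are O(1); the tiny abs.tol floor keeps the
    # near-cancelling third central moment (zero-skew shapes) integrable
    stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-13,
                     subdivisions = 500L)$value
  }
  mu <- q(function(x) x * pdf_imic(x, 1, p2))
  v <- q(function(x) (x - mu)^2 * pdf_imic(x, 1, p2))
  m3 <- q(function(x) (x - mu)^3 * pdf_imic(x, 1, p2))
  m4 <- q(function(x) (x - mu)^4 * pdf_imic(x, 1, p2))
  list(mean = p1 * mu, sd = p1 * sqrt(v),
       skewness = m3 / v^1.5, kurtosis = m4 / v^2)
}

#' Concentration at a given survival level
#'
#' Inverts the fitted survival curve: the concentration `c` at which the
#' proliferating fraction equals `eps`, i.e. \eqn{c = p_1(-\ln\eps)^{1/p_2}}.
#' Threshold concentrations of the iMIC suite are special cases:
#' `eps = 0.05` gives the concentration inhibiting growth in >95% of droplets
#' and a small `eps` (default policy 0.001) the near-complete-inhibition
#' concentration. When `c_max` is supplied and the solution lies beyond it,
#' the threshold is not determinable from the tested range and `NA` is
#' returned with attribute `status = "ND"` (mirroring heavy-tailed samples
#' whose fitted curve approaches the concentration axis only far beyond the
#' experiment's grid).
#'
#' @inheritParams gompertz_survival
#' @param eps target survival level, strictly between 0 and 1.
#' @param c_max highest concentration actually tested; `Inf` disables the
#'   not-determinable rule.
#' @return concentration (attribute `status`: `"ok"` or `"ND"`).
#' @export
solve_threshold <- function(p1, p2, eps, c_max = Inf) {
  check_shape_scale(p1, p2)
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0 || eps >= 1) {
    stop("`eps` must be a single value strictly between 0 and 1")
  }
  conc <- p1 * (-log(eps))^(1 / p2)
  if (conc > c_max) {
    return(structure(NA_real_, status = "ND"))
  }
  structure(conc, status = "ok")
}

#' Recover Weibull shape and scale from a printed mode/mean pair
#'
#' Given the mode and mean of an iMIC distribution (as reported in a summary
#' table), solves for the shape `p2` from the ratio
#' \eqn{mode/mean = (1-1/p_2)^{1/p_2} / \Gamma(1+1/p_2)} and then the scale
#' `p1` from the mean. The ratio is not injective in the shape: it rises
#' above 1, peaks, and decays back towards 1, so a ratio slightly above 1 has
#' two preimages. All roots are returned; the default pick is the smallest
#' shape, which corresponds to the wider (larger-CoV) distribution and is the
#' branch consistent with a dispersed single-cell MIC distribution. Check the
#' implied SD against any independently reported dispersion when available.
#'
#' @param mode distribution mode (> 0; requires shape > 1).
#' @param mean distribution mean (> 0).
#' @param interval search interval for the shape.
#' @return list with `p1`, `p2` (selected root) and `p2_roots` (all roots,
#'   ascending).
#' @export
solve_shape_scale <- function(mode, mean, interval = c(1.0001, 1000)) {
  if (mode <= 0 || mean <= 0) stop("`mode` and `mean` must be positive")
  ratio <- mode / mean
  g <- function(p2) (1 - 1 / p2)^(1 / p2) / gamma(1 + 1 / p2) - ratio
  k <- exp(seq(log(interval[1]), log(interval[2]), length.out = 2000L))
  v <- vapply(k, g, numeric(1))
  flips <- which(diff(sign(v)) != 0)
  if (length(flips) == 0L) {
    stop("no Weibull shape reproduces mode/mean = ", signif(ratio, 5),
         " on the search interval")
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(g, c(k[i], k[i + 1L]), tol = 1e-12)$root
  }, numeric(1))
  p2 <- min(roots)
  p1 <- mean / gamma(1 + 1 / p2)
  list(p1 = p1, p2 = p2, p2_roots = sort(roots))
}

check_shape_scale <- function(p1, p2) {
  if (length(p1) != 1L || !is.finite(p1) || p1 <= 0) {
    stop("scale `p1` must be a single positive number")
  }
  if (length(p2) != 1L || !is.finite(p2) || p2 <= 0) {
    stop("shape `p2` must be a single positive number")
  }
  invisible(TRUE)
}
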