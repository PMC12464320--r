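test_that("survival function hits its defining values and rejects bad input", {
  expect_equal(gompertz_survival(0, 10, 4), 1)
  expect_equal(gompertz_survival(10, 10, 4), exp(-1))
  expect_equal(gompertz_survival(20, 10, 2), exp(-4))
  grid <- seq(0, 50, by = 0.5)
  expect_true(all(diff(gompertz_survival(grid, 10, 4)) < 0))
  expect_error(gompertz_survival(-1, 10, 4), "non-negative")
  expect_error(gompertz_survival(1, -10, 4), "p1")
  expect_error(gompertz_survival(1, 10, 0), "p2")
})

test_that("iMIC density matches the Weibull density and normalizes", {
  # dual route: hand-written formula vs stats::dweibull
  for (p2 in c(0.7, 1, 2.5, 4.4)) {
    x <- c(0.01, 1, 5, 9.8, 20)
    expect_equal(pdf_imic(x, 9.8, p2), stats::dweibull(x, p2, 9.8),
                 tolerance = 1e-12)
  }
  # exponential special case at shape 1
  expect_equal(pdf_imic(c(0, 3), 5, 1), c(1 / 5, exp(-3 / 5) / 5))
  # integrates to 1
  for (p2 in c(0.5, 1, 4.4, 12)) {
    total <- stats::integrate(pdf_imic, 0, Inf, p1 = 9.8, p2 = p2,
                              rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # density is the negative derivative of the survival curve
  h <- 1e-6
  x <- c(2, 9.8, 15)
  num_deriv <- -(gompertz_survival(x + h, 9.8, 4.4) -
                 gompertz_survival(x - h, 9.8, 4.4)) / (2 * h)
  expect_equal(pdf_imic(x, 9.8, 4.4), num_deriv, tolerance = 1e-6)
})

test_that("mode formula agrees with the numerical argmax of the density", {
  for (p2 in c(1.5, 2, 4.4, 8, 20)) {
    m <- imic_mode(9.8, p2)
    argmax <- stats::optimize(function(x) pdf_imic(x, 9.8, p2),
                              c(0, 3 * 9.8), maximum = TRUE,
                              tol = 1e-10)$maximum
    expect_equal(m, argmax, tolerance = 1e-6 * 9.8)
  }
  expect_equal(imic_mode(9.8, 1), 0)       # mode collapses to origin
  expect_warning(imic_mode(9.8, 0.8), "monotone")
  # large shape: mode approaches the scale
  expect_equal(imic_mode(9.8, 1e4), 9.8, tolerance = 1e-3)
})

test_that("closed-form moments match quadrature and known special cases", {
  # exponential (shape 1): mean = sd = scale, skew 2, kurtosis 9
  m <- closed_form_moments(7, 1)
  expect_equal(m$mean, 7, tolerance = 1e-10)
  expect_equal(m$sd, 7, tolerance = 1e-10)
  expect_equal(m$skewness, 2, tolerance = 1e-10)
  expect_equal(m$kurtosis, 9, tolerance = 1e-10)
  # agreement with adaptive quadrature over a wide shape range
  for (p2 in c(0.5, 1, 2, 3.602, 5, 10, 20)) {
    cf <- closed_form_moments(9.8, p2, numerical_check = FALSE)
    nm <- dropletAST:::numerical_moments(9.8, p2)
    for (f in c("mean", "sd", "skewness", "kurtosis")) {
      expect_lt(abs(cf[[f]] - nm[[f]]), 1e-6 * max(1, abs(cf[[f]])))
    }
  }
  # quadrature-based error estimates are reported and tiny
  est <- closed_form_moments(9.8, 4.4)$numerical_error
  expect_named(est, c("skewness", "kurtosis"))
  expect_true(all(est < 1e-6))
})

test_that("skewness crosses zero near shape 3.602 and orders mode vs mean", {
  skew_of <- function(p2) closed_form_moments(1, p2,
                                              numerical_check = FALSE)$skewness
  root <- uniroot(skew_of, c(3, 4), tol = 1e-10)$root
  expect_equal(root, 3.602, tolerance = 1e-3)
  # mode < mean when skewness is clearly positive and vice versa; the two
  # sign changes do not coincide exactly (mean and mode cross at a slightly
  # smaller shape than the skewness zero), so the near-symmetric window
  # around 3.3-3.6 is excluded
  for (p2 in c(1.5, 2, 2.5, 3, 4.4, 6, 8)) {
    gam <- skew_of(p2)
    expect_equal(imic_mode(9.8, p2) < closed_form_moments(9.8, p2,
                   numerical_check = FALSE)$mean,
                 gam > 0)
  }
})

test_that("threshold solver inverts the curve exactly and is monotone", {
  for (eps in c(1e-6, 0.001, 0.05, exp(-1), 0.5, 0.99, 0.9999)) {
    cc <- as.numeric(solve_threshold(9.8, 4.4, eps))
    expect_equal(gompertz_survival(cc, 9.8, 4.4), eps,
                 tolerance = 1e-10)
  }
  expect_equal(as.numeric(solve_threshold(9.8, 4.4, exp(-1))), 9.8,
               tolerance = 1e-12)
  eps_grid <- c(0.001, 0.05, 0.3, 0.8, 0.99)
  cs <- vapply(eps_grid, function(e) {
    as.numeric(solve_threshold(9.8, 4.4, e))
  }, numeric(1))
  expect_true(all(diff(cs) < 0))  # deeper inhibition needs more drug
  expect_error(solve_threshold(9.8, 4.4, 0), "between 0 and 1")
  expect_error(solve_threshold(9.8, 4.4, 1), "between 0 and 1")
  # not-determinable when the solution exceeds the tested range
  nd <- solve_threshold(8, 1.3, 0.001, c_max = 20)
  expect_true(is.na(nd))
  expect_identical(attr(nd, "status"), "ND")
})

test_that("shape/scale solver round-trips and flags the ambiguous branch", {
  # forward: known parameters -> mode/mean -> recovered parameters
  for (p2_true in c(2, 4.4, 6)) {
    m <- closed_form_moments(9.8, p2_true, numerical_check = FALSE)
    sol <- solve_shape_scale(imic_mode(9.8, p2_true), m$mean)
    expect_equal(sol$p2, p2_true, tolerance = 1e-4)
    expect_equal(sol$p1, 9.8, tolerance = 1e-4)
  }
  # a mode/mean ratio slightly above 1 has two shape preimages; the default
  # pick is the smaller (wider-distribution) branch and both are reported
  sol <- solve_shape_scale(9.2, 8.9)
  expect_length(sol$p2_roots, 2)
  expect_equal(sol$p2, min(sol$p2_roots))
  expect_equal(imic_mode(sol$p1, sol$p2), 9.2, tolerance = 1e-6)
  expect_error(solve_shape_scale(2, 1), "no Weibull shape")
})
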