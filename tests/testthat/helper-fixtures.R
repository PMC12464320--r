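# noiseless profile sampled from the survival model itself
truth_profile <- function(p1, p2, grid = c(0, 2, 4, 6, 8, 9, 10, 11, 12,
                                           13, 14, 16, 18, 20)) {
  structure(
    data.frame(concentration = grid,
               f_plus = NA_real_,
               F_R = gompertz_survival(grid, p1, p2),
               sd = 0),
    n_replicates = 1L, unit = NA_character_,
    class = c("resistance_profile", "data.frame")
  )
}

# hand-built fit object for summary-level tests that need exact parameters
fake_fit <- function(p1, p2, c_max = Inf, unit = NA_character_) {
  structure(list(p1 = p1, p2 = p2, rss = 0, converged = TRUE,
                 c_max_tested = c_max, n_points = 0L, unit = unit,
                 fitted = NULL, data = NULL),
            class = "gompertz_fit")
}

# delta-method SD of F_R(c) = (N+(c)/N) / (N+(0)/N) for binomial sampling
fr_sampling_sd <- function(fr, n, p_occ) {
  q1 <- p_occ * fr   # positive fraction at c
  q0 <- p_occ        # positive fraction at 0
  fr * sqrt(pmax(0, (1 - q1) / (n * pmax(q1, 1e-12)) +
                    (1 - q0) / (n * q0)))
}

# iterative-refinement grid search minimizing the same unweighted RSS the
# optimizer minimizes; independent oracle for fit_gompertz
grid_fit <- function(conc, fr, p1_range = c(1, 30), p2_range = c(0.5, 12),
                     n = 61, rounds = 6) {
  best <- NULL
  for (it in seq_len(rounds)) {
    p1s <- seq(p1_range[1], p1_range[2], length.out = n)
    p2s <- seq(p2_range[1], p2_range[2], length.out = n)
    rss <- outer(p1s, p2s, Vectorize(function(a, b) {
      sum((fr - exp(-(conc / a)^b))^2)
    }))
    ij <- arrayInd(which.min(rss), dim(rss))
    best <- c(p1 = p1s[ij[1]], p2 = p2s[ij[2]], rss = min(rss))
    w1 <- diff(p1_range) / (n - 1); w2 <- diff(p2_range) / (n - 1)
    p1_range <- c(max(1e-6, best["p1"] - 2 * w1), best["p1"] + 2 * w1)
    p2_range <- c(max(1e-6, best["p2"] - 2 * w2), best["p2"] + 2 * w2)
  }
  best
}
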