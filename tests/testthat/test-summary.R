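test_that("threshold policy enforces the ordering of survival levels", {
  p <- threshold_policy()
  expect_true(p$eps_all < p$eps_total && p$eps_total < p$eps_start)
  expect_error(threshold_policy(eps_start = 0.04), "eps_all < eps_total")
  expect_error(threshold_policy(eps_all = 0), "eps_all")
})

test_that("experimental complete-inhibition concentration follows its rule", {
  grid <- c(0, 10, 12, 14, 16)
  t_of <- function(pos, id) count_table(grid, rep(100, 5), pos, id)
  # one replicate still grows at 12; 14 and above are clean in all three
  tabs <- list(t_of(c(90, 20, 1, 0, 0), "r1"),
               t_of(c(88, 18, 0, 0, 0), "r2"),
               t_of(c(91, 22, 0, 0, 0), "r3"))
  expect_equal(as.numeric(imic_exp(tabs)), 14)
  # a fluke all-zero below a growing concentration does not count
  fluke <- list(t_of(c(90, 0, 5, 0, 0), "r1"))
  expect_equal(as.numeric(imic_exp(fluke)), 14)
  # growth up to the top of the grid: not reached
  alive <- list(t_of(c(90, 50, 30, 10, 2), "r1"))
  expect_true(is.na(imic_exp(alive)))
  expect_identical(attr(imic_exp(alive), "status"), "not_reached")
  # simulated data: observed complete inhibition lands within one grid step
  # of where the expected positive count drops below 1
  cfg <- simulation_config(n_droplets_per_conc = 5000L, seed = 8L)
  tabs_sim <- simulate_counts(cfg)
  p_occ <- 1 - exp(-0.1)
  expected_pos <- 5000 * p_occ * gompertz_survival(cfg$conc_grid, 9.8, 4.4)
  c_lt1 <- min(cfg$conc_grid[expected_pos < 1])
  obs <- as.numeric(imic_exp(tabs_sim))
  grid_step <- diff(cfg$conc_grid)[which(cfg$conc_grid == c_lt1) - 1]
  expect_lte(abs(obs - c_lt1), grid_step)
})

test_that("the summary populates every statistic coherently", {
  fit <- fake_fit(9.8, 4.4, c_max = 20, unit = "ng/mL")
  s <- imic_summary(fit)
  expect_equal(s$imic_mode, imic_mode(9.8, 4.4))
  expect_equal(s$rmsd, s$imic_sd / s$imic_mode)
  expect_equal(s$cov, s$imic_sd / s$imic_mean)
  expect_equal(gompertz_survival(s$imic_start, 9.8, 4.4), 0.99,
               tolerance = 1e-10)
  expect_equal(gompertz_survival(s$imic_total, 9.8, 4.4), 0.05,
               tolerance = 1e-10)
  expect_identical(s$imic_all_status, "ok")
  expect_equal(s$doh, s$imic_all / s$imic_start)
  expect_identical(s$doh_source, "fitted")
  expect_gt(s$imic_kurtosis, 1)
  expect_true(all(s$numerical_error < 1e-6))
})

test_that("heavy tails switch the DoH to the experimental concentration", {
  # scale 8, shape 1.3: 99.9% inhibition needs ~35 units, far beyond c_max 20
  fit <- fake_fit(8, 1.3, c_max = 20)
  grid <- c(0, 5, 10, 20)
  tabs <- list(count_table(grid, rep(100, 4), c(60, 30, 10, 0), "r1"))
  s <- imic_summary(fit, tables = tabs)
  expect_identical(s$imic_all_status, "ND")
  expect_true(is.na(s$imic_all))
  expect_identical(s$doh_source, "experimental")
  expect_equal(s$doh, 20 / s$imic_start)
  # without raw tables the DoH is undefined, with a status saying why
  s2 <- imic_summary(fit)
  expect_true(is.na(s2$doh))
  expect_match(s2$doh_status, "not determinable")
})

test_that("degenerate shapes leave mode-based statistics undefined", {
  fit <- fake_fit(8, 0.9, c_max = 100)
  s <- suppressWarnings(imic_summary(fit))
  expect_identical(s$imic_mode, 0)
  expect_true(is.na(s$rmsd))
  expect_true(is.na(s$doh))
  expect_match(s$doh_status, "degenerates")
})

test_that("summaries are dimensionally consistent under unit rescaling", {
  # ng/mL -> pg/mL: concentrations x1000; shapes and ratios must not move
  a <- imic_summary(fake_fit(9.8, 4.4, c_max = 20), tables = NULL)
  b <- imic_summary(fake_fit(9800, 4.4, c_max = 20000), tables = NULL)
  for (f in c("imic_mode", "imic_mean", "imic_sd", "imic_start",
              "imic_total", "imic_all")) {
    expect_equal(b[[f]], 1000 * a[[f]], tolerance = 1e-9)
  }
  for (f in c("rmsd", "cov", "imic_skewness", "imic_kurtosis", "doh")) {
    expect_equal(b[[f]], a[[f]], tolerance = 1e-9)
  }
})

test_that("the summary table export mirrors the statistics layout", {
  df <- as.data.frame(imic_summary(fake_fit(9.8, 4.4, c_max = 20)))
  expect_identical(df$statistic[1], "imic_mode")
  expect_identical(nrow(df), 12L)
  expect_equal(df$value[df$statistic == "doh"],
               imic_summary(fake_fit(9.8, 4.4, c_max = 20))$doh)
})
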