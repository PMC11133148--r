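test_that("tau-b equals an O(n^2) pairwise-count oracle under heavy ties", {
  tau_oracle <- function(x, y) {
    n <- length(x)
    C <- 0; D <- 0; Tx <- 0; Ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) Tx <- Tx + 1
      else if (dy == 0) Ty <- Ty + 1
      else if (dx == dy) C <- C + 1
      else D <- D + 1
    }
    (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
  }
  set.seed(31)
  for (rep in 1:5) {
    x <- sample(1:4, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
    expect_equal(kendall_tau_b(x, y), tau_oracle(x, y), tolerance = 1e-12)
  }
  expect_equal(kendall_tau_b(1:10, 2 * (1:10)), 1)
  expect_true(is.na(kendall_tau_b(rep(1, 5), 1:5)))
  set.seed(32)
  expect_lt(abs(kendall_tau_b(rnorm(4000), rnorm(4000))), 0.05)
})

fake_sim <- function(grid, fun, n = 30, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as_scenario(grid[i, ])
    v <- fun(s, n)
    data.frame(family = s$family, estimator = s$estimator,
               n_indicators = s$n_indicators, n_options = s$n_options,
               distribution = s$distribution, loading = s$loading,
               sample_size = s$sample_size,
               factor_correlation = s$factor_correlation,
               misspec_magnitude = s$misspec_magnitude,
               misspec_proportion = s$misspec_proportion,
               chi2 = v, df = 9, chi2_df = v / 9, cfi = 1 - v / 100,
               rmsea = v / 100, srmr = v / 100, scaling_factor = 1,
               shift = 0, factor_cor = NA_real_, converged = TRUE,
               heywood = FALSE, scenario_id = grid$id[i],
               replication = seq_len(n), resamples = 0L)
  })
  structure(list(records = do.call(rbind, rows), convergence_rate = 1,
                 resample_rate = 0), class = "gof_simulation")
}

test_that("a planted linear dependence on sample size is recovered", {
  g <- enumerate_scenarios(list(dim_correct = list(
    estimator = c("ML", "DWLS"), n_indicators = c(6L, 12L),
    n_options = c(3L, 5L, 7L), distribution = c("symmetric", "asymmetric"),
    loading = c(.4, .6, .8), sample_size = c(200L, 500L, 2000L))))
  res <- fake_sim(g, function(s, n) 10 + 3 * (s$sample_size / 1000) +
                    rnorm(n, sd = 1e-6))
  out <- susceptibility_regression(res)
  expect_equal(unname(out$coefficients$chi2["size"]), -3, tolerance = 1e-3)
  expect_gt(out$r_squared["chi2"], 0.999)
})

test_that("recoding flips fitted signs for the lower-is-better indices", {
  g <- enumerate_scenarios(list(dim_correct = list(
    estimator = "ML", n_indicators = 6L, n_options = c(3L, 5L, 7L),
    distribution = "symmetric", loading = c(.4, .6, .8),
    sample_size = c(200L, 500L, 2000L))))
  res <- fake_sim(g, function(s, n) 5 + 2 * s$loading + rnorm(n, sd = 1e-6))
  out <- susceptibility_regression(res)
  # chi2 is multiplied by -1 before the fit, so the planted +2 appears as -2
  expect_equal(unname(out$coefficients$chi2["loading"]), -2, tolerance = 1e-3)
  # CFI is left in its original direction
  expect_equal(unname(out$coefficients$cfi["loading"]), -0.02,
               tolerance = 1e-4)
})

test_that("grouped medians behave and preserve constants", {
  g <- enumerate_scenarios(list(dim_correct = list(
    estimator = c("ML", "DWLS"), n_indicators = 6L, n_options = 5L,
    distribution = "symmetric", loading = c(.4, .8),
    sample_size = 200L)))
  res <- fake_sim(g, function(s, n) rep(7, n))
  med <- median_profiles(res, condition_on = c("estimator", "loading"),
                         response = "chi2")
  expect_true(all(med$median == 7))
  expect_equal(nrow(med), 4)
  expect_error(median_profiles(res, "nonexistent", "chi2"), "not present")
})
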