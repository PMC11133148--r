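test_that("categorical moments match closed forms", {
  m <- categorical_moments(rep(1/3, 3))
  expect_equal(unname(m["variance"]), 2/3)
  expect_equal(unname(m["skewness"]), 0)
  m <- categorical_moments(c(0, 1, 0))
  expect_equal(unname(m["variance"]), 0)
  expect_true(is.nan(m["skewness"]))
  m <- categorical_moments(c(.1, .2, .4, .2, .1))
  expect_equal(unname(m["skewness"]), 0)
  expect_error(categorical_moments(c(.5, .6)), "sum to 1")
})

test_that("threshold solver hits the moment targets", {
  t2 <- solve_thresholds(2, 0)
  expect_equal(t2$thresholds, 0)
  expect_equal(t2$probs, c(.5, .5))

  t5 <- solve_thresholds(5, 0, -0.80)
  expect_equal(t5$thresholds, -rev(t5$thresholds))   # exact symmetry
  expect_equal(unname(t5$moments["skewness"]), 0)
  expect_lt(abs(t5$moments["excess_kurtosis"] + 0.80), 0.05)

  # asymmetric case checked against the independent moment oracle
  t7 <- solve_thresholds(7, 0.65, -0.80)
  oracle <- categorical_moments(diff(c(0, pnorm(t7$thresholds), 1)))
  expect_lt(abs(oracle["skewness"] - 0.65), 1e-3)
  expect_lt(abs(oracle["excess_kurtosis"] + 0.80), 0.05)
  expect_true(all(diff(t7$thresholds) > 0))
})

test_that("population models implement the residual-variance rule", {
  m <- build_population_model(scn(loading = 0.6))
  expect_equal(unname(m$theta), rep(1 - 0.36, 6))

  s <- scn(family = "cross_misspec", loading = 0.6,
           factor_correlation = 0.3, misspec_magnitude = 0.2,
           misspec_proportion = 0.17)
  m <- build_population_model(s)
  # first indicator of factor 2 carries the cross-loading
  expect_equal(m$loadings[4, ], c(0.2, 0.6))
  expect_equal(unname(m$theta[4]), 1 - (0.04 + 0.36 + 2 * .2 * .6 * .3))
  expect_equal(unname(m$theta[1]), 1 - 0.36)

  # degenerate: cross-loading too large for unit indicator variance
  bad <- scn(family = "cross_misspec", loading = 0.8,
             factor_correlation = 0.3, misspec_magnitude = 0.3,
             misspec_proportion = 0.33)
  bad$loading <- 0.9
  bad$misspec_magnitude <- 0.9
  expect_error(build_population_model(bad), "residual variance")
})

test_that("simulated datasets are deterministic, in range, and accepted", {
  s <- scn(n_options = 7L, distribution = "asymmetric", loading = 0.4)
  d1 <- sim_for(s, seed = 11)
  d2 <- sim_for(s, seed = 11)
  expect_identical(d1$values, d2$values)
  expect_true(all(d1$values %in% 1:7))
  counts <- apply(d1$values, 2, tabulate, nbins = 7)
  expect_gte(min(counts), 5)
})

test_that("discretization is monotone and preserves latent correlations", {
  s <- scn(loading = 0.8, sample_size = 2000L)
  d <- sim_for(s, seed = 3, latent = TRUE)
  # monotone: larger latent response -> weakly larger code, per column
  for (j in c(1, 4)) {
    ord <- order(d$latent[, j])
    expect_true(all(diff(d$values[ord, j]) >= 0))
  }
  # pre-discretization correlation of two indicators is lambda^2 = .64
  expect_lt(abs(cor(d$latent[, 1], d$latent[, 2]) - 0.64), 0.05)
  # population correlation matrix of the latent responses is Lambda Phi Lambda'
  m <- build_population_model(s)
  pop <- m$loadings %*% m$phi %*% t(m$loadings)
  diag(pop) <- 1
  expect_lt(max(abs(cor(d$latent) - pop)), 0.06)
})

test_that("resampling is most frequent in the sparse corner", {
  s_hard <- scn(n_options = 7L, distribution = "asymmetric", loading = 0.4,
                sample_size = 200L)
  s_easy <- scn(n_options = 5L, distribution = "symmetric", loading = 0.4,
                sample_size = 2000L)
  hard <- mean(sapply(1:30, function(i) sim_for(s_hard, i)$resamples > 0))
  easy <- mean(sapply(1:30, function(i) sim_for(s_easy, i)$resamples > 0))
  expect_gte(hard, easy)
  expect_gt(hard, 0)
})

test_that("ordinal CSV round-trips", {
  d <- sim_for(scn(), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_ordinal_csv(d, path)
  d2 <- read_ordinal_csv(path, n_options = d$n_options)
  expect_equal(unname(d2$values), unname(d$values))
  unlink(path)
})
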