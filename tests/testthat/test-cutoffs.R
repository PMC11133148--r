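# synthetic record sets let the cutoff logic be tested without refitting
fake_records <- function(id, n = 200, seed = 1,
                         family = "dim_correct") {
  set.seed(seed)
  s <- parse_scenario_id(id)
  data.frame(
    family = family, estimator = s$estimator, n_indicators = s$n_indicators,
    n_options = s$n_options, distribution = s$distribution,
    loading = s$loading, sample_size = s$sample_size,
    factor_correlation = s$factor_correlation,
    misspec_magnitude = s$misspec_magnitude,
    misspec_proportion = s$misspec_proportion,
    chi2 = rchisq(n, 9), df = 9, chi2_df = rchisq(n, 9) / 9,
    cfi = 1 - rbeta(n, 1, 30), rmsea = rbeta(n, 1, 30) / 2,
    srmr = rbeta(n, 2, 40), scaling_factor = 1, shift = 0,
    factor_cor = NA_real_, converged = TRUE, heywood = FALSE,
    scenario_id = id, replication = seq_len(n), resamples = 0L)
}

id_ok <- scenario_id(scn())

test_that("cutoffs are the Type-I-error-controlling quantiles", {
  rec <- fake_records(id_ok)
  tab <- derive_cutoffs(rec, alpha = 0.05)
  expect_equal(tab$chi2, quantile(rec$chi2, .95, names = FALSE))
  expect_equal(tab$cfi, quantile(rec$cfi, .05, names = FALSE))
  # degenerate distribution: the cutoff is the constant
  rec2 <- rec
  for (g in c("chi2", "chi2_df", "cfi", "rmsea", "srmr")) rec2[[g]] <- 0.42
  tab2 <- derive_cutoffs(rec2, alpha = 0.17)
  expect_true(all(unlist(tab2[c("chi2", "chi2_df", "cfi", "rmsea",
                                "srmr")]) == 0.42))
  # stricter alpha gives stricter cutoffs
  t01 <- derive_cutoffs(rec, alpha = 0.01)
  t05 <- derive_cutoffs(rec, alpha = 0.05)
  expect_gt(t01$chi2, t05$chi2)
  expect_lt(t01$cfi, t05$cfi)
})

test_that("cutoffs refuse misspecified records and empty input", {
  bad <- fake_records(scenario_id(scn(family = "dim_misspec",
                                      factor_correlation = 0.5)),
                      family = "dim_misspec")
  expect_error(derive_cutoffs(bad), "misspecified")
  none <- fake_records(id_ok)
  none$converged <- FALSE
  expect_error(derive_cutoffs(none), "zero converged")
})

test_that("self-scored rejection rates equal alpha within 1/n_reps", {
  rec <- fake_records(id_ok, n = 1000)
  tab <- derive_cutoffs(rec, alpha = 0.05)
  rates <- rejection_rates(rec, tab)
  expect_equal(rates$kind, "type1")
  for (g in c("chi2", "chi2_df", "cfi", "rmsea", "srmr"))
    expect_lt(abs(rates[[g]] - 0.05), 1 / 1000 + 1e-12)
})

test_that("misspecified cells are scored against their correct twin", {
  mis_id <- scenario_id(scn(family = "cross_misspec",
                            factor_correlation = 0.3,
                            misspec_magnitude = 0.2,
                            misspec_proportion = 0.17))
  twin <- gofcutoffs:::.twin_correct_id(mis_id)
  expect_equal(parse_scenario_id(twin)$family, "cross_correct")
  expect_equal(parse_scenario_id(twin)$factor_correlation, 0.3)

  cor_rec <- fake_records(twin, family = "cross_correct", seed = 2)
  tab <- derive_cutoffs(cor_rec)
  mis_rec <- fake_records(mis_id, family = "cross_misspec", seed = 3)
  rates <- rejection_rates(mis_rec, tab)
  expect_equal(rates$kind, "type2")
  expect_true(all(unlist(rates[c("chi2", "cfi")]) >= 0 &
                    unlist(rates[c("chi2", "cfi")]) <= 1))
  # a scenario without a twin cutoff errors
  expect_error(rejection_rates(mis_rec, tab[0, ]), "no cutoffs")
})

test_that("the shipped coefficient table matches its source digit for digit", {
  path <- system.file("extdata", "cutoff_regression_coefficients.csv",
                      package = "gofcutoffs")
  raw <- read.csv(path, colClasses = "character",
                  na.strings = character(0))
  tab <- cutoff_regression_table()
  expect_equal(nrow(tab$coefficients), 74)
  for (g in c("chi2", "chi2_df", "cfi", "rmsea", "srmr")) {
    shipped <- raw[[g]][!raw$term %in% c("r_squared", "n_cells")]
    loaded <- tab$coefficients[[g]]
    expect_identical(is.na(loaded), shipped == "NA")
    expect_identical(sprintf("%.5f", loaded[!is.na(loaded)]),
                     sprintf("%.5f", as.numeric(shipped[shipped != "NA"])))
  }
  expect_true(all(tab$r_squared >= 0.810))
  # spot checks against independently transcribed entries
  co <- tab$coefficients
  expect_identical(co$cfi[co$term == "intercept"], -0.53129)
  expect_identical(co$rmsea[co$term == "loading_x_size"], 0.01187)
  expect_identical(co$chi2[co$term == "est_dwls_x_loading"], -41.99689)
  expect_true(is.na(co$srmr[co$term == "est_mlr"]))
})

test_that("predicted cutoffs equal an independent term-by-term summation", {
  co <- cutoff_regression_table()$coefficients
  b <- function(term, g) {
    v <- co[[g]][co$term == term]
    if (is.na(v)) 0 else v
  }
  # hand-rolled evaluation for ML, 6 indicators, 5 options, symmetric,
  # loading .60, N = 200, one factor, uncorrelated
  hand <- function(g) {
    sz <- 200 / 1000
    b("intercept", g) +
      b("indicators", g) * 6 + b("options", g) * 5 +
      b("options_sq", g) * 25 + b("loading", g) * 0.6 +
      b("loading_sq", g) * 0.36 + b("size", g) * sz +
      b("size_sq", g) * sz^2 + b("factors", g) * 1 +
      b("indicators_x_options", g) * 6 * 5 +
      b("indicators_x_options_sq", g) * 6 * 25 +
      b("indicators_x_loading", g) * 6 * 0.6 +
      b("indicators_x_loading_sq", g) * 6 * 0.36 +
      b("indicators_x_size", g) * 6 * sz +
      b("indicators_x_size_sq", g) * 6 * sz^2 +
      b("indicators_x_factors", g) * 6 +
      b("options_x_loading", g) * 5 * 0.6 +
      b("options_x_loading_sq", g) * 5 * 0.36 +
      b("options_x_size", g) * 5 * sz +
      b("options_x_size_sq", g) * 5 * sz^2 +
      b("options_x_factors", g) * 5 +
      b("options_sq_x_loading", g) * 25 * 0.6 +
      b("options_sq_x_loading_sq", g) * 25 * 0.36 +
      b("options_sq_x_size", g) * 25 * sz +
      b("options_sq_x_size_sq", g) * 25 * sz^2 +
      b("options_sq_x_factors", g) * 25 +
      b("loading_x_size", g) * 0.6 * sz +
      b("loading_x_size_sq", g) * 0.6 * sz^2 +
      b("loading_x_factors", g) * 0.6 +
      b("loading_sq_x_size", g) * 0.36 * sz +
      b("loading_sq_x_size_sq", g) * 0.36 * sz^2 +
      b("loading_sq_x_factors", g) * 0.36 +
      b("size_x_factors", g) * sz + b("size_sq_x_factors", g) * sz^2
  }
  pred <- predict_cutoffs("ML", 6, 5, "symmetric", 0.6, 200, 1, FALSE)
  for (g in c("chi2", "chi2_df", "cfi", "rmsea", "srmr"))
    expect_equal(unname(pred[[g]]), hand(g), tolerance = 1e-10)
})

test_that("SRMR predictions collapse the estimator pairs", {
  p_dwls <- predict_cutoffs("DWLS", 6, 5, "symmetric", 0.6, 200)
  p_wlsmv <- predict_cutoffs("WLSMV", 6, 5, "symmetric", 0.6, 200)
  p_ml <- predict_cutoffs("ML", 6, 5, "symmetric", 0.6, 200)
  p_mlr <- predict_cutoffs("MLR", 6, 5, "symmetric", 0.6, 200)
  expect_equal(p_wlsmv[["srmr"]], p_dwls[["srmr"]])
  expect_equal(p_mlr[["srmr"]], p_ml[["srmr"]])
  expect_false(p_wlsmv[["cfi"]] == p_dwls[["cfi"]])
  expect_error(predict_cutoffs("ULS", 6, 5, "symmetric", 0.6, 200),
               "estimator")
  expect_error(predict_cutoffs("ML", 6, 5, "symmetric", 0.6, 200,
                               n_factors = 3), "factors")
  expect_warning(predict_cutoffs("ML", 20, 5, "symmetric", 0.6, 200),
                 "extrapolating")
})

test_that("predicted CFI cutoffs increase with loading magnitude", {
  cuts <- sapply(c(0.4, 0.6, 0.8), function(l)
    predict_cutoffs("ML", 6, 7, "asymmetric", l, 200)[["cfi"]])
  expect_true(all(diff(cuts) > 0))
})

test_that("the cutoff regression recovers a planted coefficient set", {
  # build a cutoff table over a crossed sub-grid, with responses generated
  # from the shipped coefficients themselves: OLS must recover them exactly
  g <- enumerate_scenarios(list(
    dim_correct = list(estimator = c("ML", "MLR", "DWLS", "WLSMV"),
                       n_indicators = c(6L, 12L), n_options = c(3L, 5L, 7L),
                       distribution = c("symmetric", "asymmetric"),
                       loading = c(.4, .6, .8),
                       sample_size = c(200L, 500L, 2000L)),
    cross_correct = list(estimator = c("ML", "MLR", "DWLS", "WLSMV"),
                         n_indicators = c(6L, 12L), n_options = c(3L, 5L, 7L),
                         distribution = c("symmetric", "asymmetric"),
                         loading = c(.4, .6, .8),
                         sample_size = c(200L, 500L, 2000L),
                         factor_correlation = c(0, 0.3))))
  tab <- data.frame(scenario_id = g$id)
  for (gof in c("chi2", "chi2_df", "cfi", "rmsea", "srmr")) {
    tab[[gof]] <- vapply(seq_len(nrow(g)), function(i) {
      est <- g$estimator[i]
      if (gof == "srmr" && est %in% c("MLR", "WLSMV")) return(NA_real_)
      unname(predict_cutoffs(
        est, g$n_indicators[i], g$n_options[i], g$distribution[i],
        g$loading[i], g$sample_size[i],
        n_factors = if (g$family[i] == "dim_correct") 1 else 2,
        correlated = isTRUE(g$factor_correlation[i] > 0))[[gof]])
    }, numeric(1))
  }
  tab$alpha <- 0.05
  tab$n_effective <- 1000L
  class(tab) <- c("cutoff_table", "data.frame")
  fitted <- fit_cutoff_regression(tab)
  shipped <- cutoff_regression_table()$coefficients
  for (gof in c("chi2", "chi2_df", "cfi", "rmsea", "srmr")) {
    ok <- !is.na(shipped[[gof]])
    expect_equal(fitted$coefficients[[gof]][ok], shipped[[gof]][ok],
                 tolerance = 1e-8)
  }
  expect_error(fit_cutoff_regression(tab[1, ]), "underdetermined")
})
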