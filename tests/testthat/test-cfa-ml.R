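spec1 <- function(p) list(n_factors = 1L, assignment = rep(1L, p),
                          correlation_mode = "absent")

test_that("ML discrepancy is zero when the sample moments lie in the model", {
  lam <- c(.7, .6, .5, .8, .6, .7)
  Sigma0 <- outer(lam, lam); diag(Sigma0) <- 1
  X <- exact_cov_data(400, Sigma0, seed = 2)
  fit <- fit_ml(X, spec1(6))
  expect_true(fit$converged)
  expect_lt(fit$T, 1e-5)
  expect_equal(fit$df, 9)
  expect_lt(max(abs(fit$estimates$std_loadings[, 1] - lam)), 1e-3)
})

test_that("a just-identified one-factor model on p = 3 is saturated", {
  lam <- c(.7, .6, .5)
  Sigma0 <- outer(lam, lam); diag(Sigma0) <- 1
  X <- exact_cov_data(300, Sigma0, seed = 3)
  fit <- fit_ml(X, spec1(3))
  expect_equal(fit$df, 0)
  expect_lt(fit$T, 1e-4)
})

test_that("ML recovers population loadings on continuous data at N = 2000", {
  d <- sim_for(scn(loading = 0.6, sample_size = 2000L), seed = 8,
               latent = TRUE)
  fit <- fit_ml(d$latent, spec1(6))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates$std_loadings[, 1] - 0.6)), 0.05)
})

test_that("baseline is the independence model and dominates the target", {
  d <- sim_for(scn(), seed = 12)
  fit <- fit_ml(d, spec1(6))
  base <- fit_baseline(d, "ML")
  expect_equal(base$df, 15)
  expect_gte(base$T, fit$T)
  expect_equal(unname(diag(base$implied_matrix)),
               unname(diag(base$sample_matrix)))
})

test_that("MLR scaling is near 1 for normal data and matches a brute-force
           assembly of tr(U Gamma) / df", {
  lam <- rep(.7, 6)
  Sigma0 <- outer(lam, lam); diag(Sigma0) <- 1
  X <- exact_cov_data(1500, Sigma0, seed = 5)
  fit <- fit_ml(X, spec1(6))
  rob <- robustify_mlr(fit, X)
  expect_lt(abs(rob$scaling_factor - 1), 0.1)

  # brute-force oracle on a small ordinal dataset: assemble Gamma and the
  # normal-theory weight matrix element by element from first principles
  d <- sim_for(scn(), seed = 6)
  fit <- fit_ml(d, spec1(6))
  rob <- robustify_mlr(fit, d)

  X <- matrix(as.numeric(d$values), d$n)
  n <- nrow(X); p <- ncol(X)
  Z <- sweep(X, 2, colMeans(X))
  ij <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  q <- nrow(ij)
  S <- crossprod(Z) / n
  Gamma <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in seq_len(q)) {
    i <- ij[a, 1]; j <- ij[a, 2]; k <- ij[b, 1]; l <- ij[b, 2]
    Gamma[a, b] <- mean(Z[, i] * Z[, j] * Z[, k] * Z[, l]) -
      S[i, j] * S[k, l]
  }
  Sinv <- solve(fit$implied_matrix)
  W <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in seq_len(q)) {
    i <- ij[a, 1]; j <- ij[a, 2]; k <- ij[b, 1]; l <- ij[b, 2]
    W[a, b] <- 0.5 * (Sinv[i, k] * Sinv[j, l] + Sinv[i, l] * Sinv[j, k])
    # duplication scaling for off-diagonal moment pairs
    if (i != j) W[a, b] <- W[a, b] * 2
    if (k != l) W[a, b] <- W[a, b] * 2
    W[a, b] <- W[a, b] / 2
  }
  Delta <- gofcutoffs:::.ml_delta(fit)
  WD <- W %*% Delta
  U <- W - WD %*% solve(t(Delta) %*% WD, t(WD))
  c_oracle <- sum(diag(U %*% Gamma)) / fit$df
  expect_equal(rob$scaling_factor, c_oracle, tolerance = 1e-6)
})

test_that("robust scaling leaves SRMR unchanged and df = 0 is a no-op", {
  d <- sim_for(scn(), seed = 13)
  fit <- fit_ml(d, spec1(6))
  rob <- robustify_mlr(fit, d)
  expect_identical(compute_srmr(fit$sample_matrix, fit$implied_matrix),
                   compute_srmr(rob$sample_matrix, rob$implied_matrix))
  expect_false(fit$T == rob$T)

  lam3 <- c(.7, .6, .5)
  Sig3 <- outer(lam3, lam3); diag(Sig3) <- 1
  X3 <- exact_cov_data(200, Sig3, seed = 4)
  f3 <- fit_ml(X3, spec1(3))
  expect_warning(r3 <- robustify_mlr(f3, X3), "df = 0")
  expect_equal(r3$T, f3$T)
})
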