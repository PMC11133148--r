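# shared fixtures: tiny scenarios and cached simulation pieces

scn <- function(family = "dim_correct", estimator = "ML", n_indicators = 6L,
                n_options = 5L, distribution = "symmetric", loading = 0.6,
                sample_size = 200L, factor_correlation = NULL,
                misspec_magnitude = NULL, misspec_proportion = NULL) {
  as_scenario(list(
    family = family, estimator = estimator, n_indicators = n_indicators,
    n_options = n_options, distribution = distribution, loading = loading,
    sample_size = sample_size, factor_correlation = factor_correlation,
    misspec_magnitude = misspec_magnitude,
    misspec_proportion = misspec_proportion))
}

# threshold sets are deterministic; cache them across tests
.thr_cache <- new.env()
thr_for <- function(K, skew = 0) {
  key <- paste(K, skew)
  if (is.null(.thr_cache[[key]]))
    .thr_cache[[key]] <- solve_thresholds(K, skew, -0.80)
  .thr_cache[[key]]
}

sim_for <- function(s, seed = 1, latent = FALSE) {
  simulate_dataset(build_population_model(s),
                   thr_for(s$n_options,
                           if (s$distribution == "asymmetric") 0.65 else 0),
                   s$sample_size, seed, latent = latent)
}

# continuous multivariate-normal data with an exact sample covariance
exact_cov_data <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  Z <- matrix(rnorm(n * p), n)
  Z <- sweep(Z, 2, colMeans(Z))
  S <- crossprod(Z) / n
  Z %*% solve(chol(S)) %*% chol(Sigma)
}
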