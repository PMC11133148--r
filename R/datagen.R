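#' Exact moments of an integer-score categorical distribution
#'
#' Scores are `1..K` with probabilities `probs`.
#'
#' @param probs Numeric vector of category probabilities (non-negative,
#'   summing to one).
#' @return Named vector with `mean`, `variance`, `skewness` and
#'   `excess_kurtosis` (the latter two `NaN` for a point mass).
#' @examples
#' categorical_moments(rep(1/3, 3))   # variance 2/3, skewness 0
#' @export
categorical_moments <- function(probs) {
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be non-negative and sum to 1", call. = FALSE)
  probs <- pmax(probs, 0)
  k <- seq_along(probs)
  m <- sum(probs * k)
  d <- k - m
  v <- sum(probs * d^2)
  skew <- if (v > 0) sum(probs * d^3) / v^1.5 else NaN
  kurt <- if (v > 0) sum(probs * d^4) / v^2 - 3 else NaN
  c(mean = m, variance = v, skewness = skew, excess_kurtosis = kurt)
}

# moments of the categorical distribution implied by logits (internal)
.probs_from_logits <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Solve category thresholds matching target moments
#'
#' Finds `K - 1` strictly increasing cutpoints on the standard-normal scale
#' whose implied category probabilities (successive differences of the normal
#' CDF) give the integer-score distribution `1..K` the requested skewness and
#' excess kurtosis. Probabilities are parameterized directly (softmax over
#' free logits) and the squared deviation of (skewness, excess kurtosis) from
#' the targets is minimized; for symmetric targets the probability vector is
#' symmetric by construction, so the skewness is exactly zero and the
#' thresholds are exactly symmetric about zero.
#'
#' @param n_options Number of response categories `K >= 2`.
#' @param target_skew Target skewness (0 for the symmetric design cell,
#'   0.65 for the asymmetric one).
#' @param target_excess_kurtosis Target excess kurtosis (about -0.80 in the
#'   built-in design).
#' @param tol Maximum tolerated absolute deviation of the achieved skewness
#'   from its target (default 1e-3); kurtosis is allowed 0.05.
#' @return An object of class `threshold_set`: list with `n_options`,
#'   `thresholds`, `probs`, `moments`, `target_skew`,
#'   `target_excess_kurtosis`.
#' @export
solve_thresholds <- function(n_options, target_skew = 0,
                             target_excess_kurtosis = -0.80, tol = 1e-3) {
  K <- as.integer(n_options)
  if (K < 2) stop("n_options must be >= 2", call. = FALSE)
  symmetric <- abs(target_skew) < 1e-12

  if (K == 2) {
    if (!symmetric)
      stop("two categories cannot carry nonzero skewness of scores 1..2 ",
           "other than via unequal probabilities; kurtosis is then fixed -- ",
           "use K >= 3 for moment targets", call. = FALSE)
    probs <- c(0.5, 0.5)
  } else if (symmetric) {
    m <- K %/% 2                       # free half-logits
    build <- function(a) {
      full <- if (K %% 2 == 0) c(a, rev(a)) else c(a, 0, rev(a))
      .probs_from_logits(full)
    }
    obj <- function(a) {
      mo <- categorical_moments(build(a))
      (mo["excess_kurtosis"] - target_excess_kurtosis)^2
    }
    best <- NULL
    for (start in list(rep(0, m), seq(-0.5, 0.5, length.out = m),
                       seq(0.5, -0.5, length.out = m))) {
      fit <- stats::optim(start, obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    probs <- build(best$par)
  } else {
    build <- function(a) .probs_from_logits(c(a, 0))
    obj <- function(a) {
      mo <- categorical_moments(build(a))
      (mo["skewness"] - target_skew)^2 +
        (mo["excess_kurtosis"] - target_excess_kurtosis)^2
    }
    best <- NULL
    for (shift in c(0, 0.4, -0.4, 0.8)) {
      start <- seq(shift, -shift, length.out = K - 1)
      fit <- stats::optim(start, obj, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    probs <- build(best$par)
  }

  mo <- categorical_moments(probs)
  if (abs(mo["skewness"] - target_skew) > tol)
    stop(sprintf(paste0("threshold solver did not reach the skewness target ",
                        "(achieved %.4f, target %.4f); consider relaxing the ",
                        "kurtosis target"), mo["skewness"], target_skew),
         call. = FALSE)
  # K = 2 has no freedom beyond symmetry: its excess kurtosis is fixed at -2
  if (K > 2 && abs(mo["excess_kurtosis"] - target_excess_kurtosis) > 0.05)
    stop(sprintf(paste0("threshold solver did not reach the kurtosis target ",
                        "(achieved %.3f, target %.3f)"),
                 mo["excess_kurtosis"], target_excess_kurtosis), call. = FALSE)
  tau <- stats::qnorm(cumsum(probs[-K]))
  if (symmetric) tau <- (tau - rev(tau)) / 2   # exact symmetry
  structure(list(n_options = K, thresholds = tau, probs = as.numeric(probs),
                 moments = mo, target_skew = target_skew,
                 target_excess_kurtosis = target_excess_kurtosis),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> K=%d  skew=%.3f  ex.kurt=%.3f\n", x$n_options,
              x$moments["skewness"], x$moments["excess_kurtosis"]))
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " "),
      "\n")
  invisible(x)
}

#' Build the population model for a scenario
#'
#' Realizes the family topology: one factor (dim_correct), two correlated
#' factors analysed as one (dim_misspec), two factors with or without
#' cross-loadings (cross families). Factor variances are 1 and each
#' indicator's implied variance is 1, so residual variances follow
#' `theta = 1 - (l1^2 + l2^2 + 2 l1 l2 r)`. Cross-loadings of magnitude
#' `misspec_magnitude` are placed on the first [cross_loading_count()]
#' indicators of factor 2, loading on factor 1.
#'
#' @param s A `scenario` (or coercible).
#' @return Object of class `population_model`: `loadings` (p x f),
#'   `phi` (factor correlation matrix), `theta` (residual variances).
#' @export
build_population_model <- function(s) {
  s <- as_scenario(s)
  p <- s$n_indicators
  one_factor_pop <- s$family == "dim_correct"
  f <- if (one_factor_pop) 1L else 2L
  lambda <- matrix(0, p, f)
  if (one_factor_pop) {
    lambda[, 1] <- s$loading
    phi <- matrix(1, 1, 1)
  } else {
    half <- p %/% 2
    lambda[seq_len(half), 1] <- s$loading
    lambda[half + seq_len(half), 2] <- s$loading
    r <- s$factor_correlation
    phi <- matrix(c(1, r, r, 1), 2, 2)
    if (s$family == "cross_misspec") {
      k <- cross_loading_count(s$misspec_proportion, p)
      if (k > 0) lambda[half + seq_len(k), 1] <- s$misspec_magnitude
    }
  }
  implied <- lambda %*% phi %*% t(lambda)
  theta <- 1 - diag(implied)
  if (any(theta <= 0))
    stop("non-positive residual variance implied for indicator(s) ",
         paste(which(theta <= 0), collapse = ", "),
         "; loadings/correlation are inconsistent with unit indicator variance",
         call. = FALSE)
  structure(list(loadings = lambda, phi = phi, theta = theta),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d indicators, %d factor(s)\n",
              nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' Analysis model implied by a scenario
#'
#' The analysis model never contains cross-loadings; misfit arises from
#' omission. dim-family scenarios are analysed with one factor; cross-family
#' scenarios with two factors whose correlation is estimated when the design
#' correlation is .30 and fixed to zero when it is .00.
#'
#' @param s A `scenario`.
#' @return List with `n_factors`, `assignment` (factor index per indicator)
#'   and `correlation_mode` (`"absent"`, `"fixed_zero"` or `"estimated"`).
#' @export
analysis_model_spec <- function(s) {
  s <- as_scenario(s)
  p <- s$n_indicators
  if (startsWith(s$family, "dim")) {
    list(n_factors = 1L, assignment = rep(1L, p), correlation_mode = "absent")
  } else {
    half <- p %/% 2
    mode <- if (abs(s$factor_correlation) < 1e-12) "fixed_zero" else "estimated"
    list(n_factors = 2L, assignment = rep(1:2, each = half),
         correlation_mode = mode)
  }
}

# deterministic 31-bit stream seed from a master seed and string context
derive_seed <- function(master_seed, ...) {
  ctx <- paste(c(master_seed, ...), collapse = "|")
  h <- as.numeric(master_seed) %% 2147483647
  for (b in utf8ToInt(ctx)) h <- (h * 48271 + b) %% 2147483647
  as.integer(h)
}

#' Simulate an ordinal dataset from a population model
#'
#' Draws correlated standard-normal factors and independent normal residuals,
#' forms unit-variance continuous indicators and discretizes each by the
#' threshold set. The whole dataset is regenerated (continuing the seeded
#' stream) until every category of every column holds at least five
#' observations, a requirement of threshold estimation for the categorical
#' estimators; the number of regenerations is recorded.
#'
#' @param model A `population_model`.
#' @param thresholds A `threshold_set`.
#' @param n Sample size.
#' @param seed Integer seed for this dataset's stream.
#' @param min_cell Minimum per-category count per column (default 5).
#' @param max_attempts Resampling cap (default 1000).
#' @param latent If `TRUE`, also return the continuous indicators.
#' @return Object of class `ordinal_dataset`: `values` (n x p integer matrix
#'   of codes `1..K`), `n`, `n_options`, `resamples`, `seed`, and optionally
#'   `latent`.
#' @export
simulate_dataset <- function(model, thresholds, n, seed, min_cell = 5,
                             max_attempts = 1000, latent = FALSE) {
  stopifnot(inherits(model, "population_model"),
            inherits(thresholds, "threshold_set"))
  p <- nrow(model$loadings)
  K <- thresholds$n_options
  tau <- thresholds$thresholds
  Lchol <- chol(model$phi)
  sd_e <- sqrt(model$theta)
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_attempts)) {
    Fm <- matrix(stats::rnorm(n * ncol(model$loadings)), n) %*% Lchol
    E <- matrix(stats::rnorm(n * p), n) %*% diag(sd_e, p)
    Y <- Fm %*% t(model$loadings) + E
    X <- matrix(findInterval(Y, tau) + 1L, n, p)
    counts <- apply(X, 2, tabulate, nbins = K)
    if (min(counts) >= min_cell) {
      out <- structure(list(values = X, n = n, n_options = K,
                            resamples = attempt - 1L, seed = as.integer(seed)),
                       class = "ordinal_dataset")
      if (latent) out$latent <- Y
      return(out)
    }
  }
  worst <- which(counts == min(counts), arr.ind = TRUE)[1, ]
  stop(sprintf(paste0("resampling cap (%d) exceeded: category %d of column ",
                      "%d stayed below %d observations"),
               max_attempts, worst[1], worst[2], min_cell), call. = FALSE)
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("<ordinal_dataset> n=%d, p=%d, K=%d, resamples=%d\n",
              x$n, ncol(x$values), x$n_options, x$resamples))
  invisible(x)
}

#' Write/read an ordinal dataset as CSV of integer codes
#' @param x An `ordinal_dataset`.
#' @param path Output path.
#' @export
write_ordinal_csv <- function(x, path) {
  df <- as.data.frame(x$values)
  names(df) <- paste0("x", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ordinal_csv
#' @param n_options Category count `K` (inferred from the data maximum when
#'   missing).
#' @export
read_ordinal_csv <- function(path, n_options = NULL) {
  df <- utils::read.csv(path)
  X <- as.matrix(df)
  storage.mode(X) <- "integer"
  K <- if (is.null(n_options)) max(X) else as.integer(n_options)
  if (min(X) < 1 || max(X) > K)
    stop("codes outside 1..K in ", path, call. = FALSE)
  structure(list(values = X, n = nrow(X), n_options = K, resamples = 0L,
                 seed = NA_integer_), class = "ordinal_dataset")
}
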