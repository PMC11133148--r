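# Maximum-likelihood CFA on raw integer codes treated as numeric.
#
# Identification: the first loading of each factor is fixed to 1, factor
# variances (and the factor covariance, when estimated) are free, residual
# variances are free. The discrepancy is
#   F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p
# with S the divisor-N sample covariance, and T = N * F at the optimum.

# parameter vector layout helpers ------------------------------------------
.ml_layout <- function(p, spec) {
  nf <- spec$n_factors
  first <- vapply(seq_len(nf), function(f) which(spec$assignment == f)[1],
                  integer(1))
  free_load <- which(!seq_len(p) %in% first)
  est_cov <- spec$correlation_mode == "estimated"
  list(nf = nf, first = first, free_load = free_load, est_cov = est_cov,
       n_par = length(free_load) + nf + as.integer(est_cov) + p,
       idx_load = seq_along(free_load),
       idx_psi = length(free_load) + seq_len(nf),
       idx_cov = if (est_cov) length(free_load) + nf + 1L else integer(0),
       idx_theta = length(free_load) + nf + as.integer(est_cov) + seq_len(p))
}

.ml_unpack <- function(par, p, spec, lay) {
  lambda <- matrix(0, p, lay$nf)
  lambda[cbind(lay$first, seq_len(lay$nf))] <- 1
  lambda[cbind(lay$free_load, spec$assignment[lay$free_load])] <-
    par[lay$idx_load]
  psi <- diag(exp(par[lay$idx_psi]), lay$nf)
  if (lay$est_cov) psi[1, 2] <- psi[2, 1] <- par[lay$idx_cov]
  theta <- exp(par[lay$idx_theta])
  list(lambda = lambda, psi = psi, theta = theta)
}

.ml_sigma <- function(pp) pp$lambda %*% pp$psi %*% t(pp$lambda) + diag(pp$theta)

#' Fit a CFA model by maximum likelihood
#'
#' Treats the integer codes as numeric scores. Non-convergence is flagged,
#' not an error; downstream summaries cull flagged fits.
#'
#' @param data An `ordinal_dataset` or numeric matrix.
#' @param spec Analysis model from [analysis_model_spec()] (fields
#'   `n_factors`, `assignment`, `correlation_mode`).
#' @return Object of class `cfa_fit` with parameter estimates, the test
#'   statistic `T` (`N * F_ML`), `df`, sample and implied covariance
#'   matrices, and a convergence flag.
#' @export
fit_ml <- function(data, spec) {
  X <- if (inherits(data, "ordinal_dataset")) data$values else data
  X <- matrix(as.numeric(X), nrow(X), ncol(X))
  n <- nrow(X); p <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n
  lds <- determinant(S, logarithm = TRUE)
  if (lds$sign <= 0) stop("singular sample covariance matrix", call. = FALSE)
  logdetS <- as.numeric(lds$modulus)
  lay <- .ml_layout(p, spec)

  objgrad <- function(par, want_grad = TRUE) {
    pp <- .ml_unpack(par, p, spec, lay)
    Sigma <- .ml_sigma(pp)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(list(value = 1e10, grad = rep(0, length(par))))
    Sinv <- chol2inv(R)
    val <- 2 * sum(log(diag(R))) + sum(Sinv * S) - logdetS - p
    if (!want_grad) return(list(value = val))
    G <- Sinv - Sinv %*% S %*% Sinv          # dF = tr(G dSigma)
    g <- numeric(length(par))
    GLP <- G %*% pp$lambda %*% pp$psi
    g[lay$idx_load] <- 2 * GLP[cbind(lay$free_load,
                                     spec$assignment[lay$free_load])]
    GL <- G %*% pp$lambda
    for (f in seq_len(lay$nf))
      g[lay$idx_psi[f]] <- sum(pp$lambda[, f] * GL[, f]) * pp$psi[f, f]
    if (lay$est_cov)
      g[lay$idx_cov] <- 2 * sum(pp$lambda[, 1] * GL[, 2])
    g[lay$idx_theta] <- diag(G) * pp$theta
    list(value = val, grad = g)
  }

  # starting values: free loadings at the population ratio 1 under
  # first-loading-fixed identification; factor variance from the mean
  # within-factor covariance; residuals at half the sample variances
  start <- numeric(lay$n_par)
  start[lay$idx_load] <- 1
  for (f in seq_len(lay$nf)) {
    members <- which(spec$assignment == f)
    offd <- S[members, members][upper.tri(diag(length(members)))]
    start[lay$idx_psi[f]] <- log(max(mean(offd), 0.05))
  }
  if (lay$est_cov) start[lay$idx_cov] <- 0
  start[lay$idx_theta] <- log(pmax(diag(S) / 2, 0.05))

  opt <- tryCatch(
    stats::nlminb(start, function(par) objgrad(par, FALSE)$value,
                  gradient = function(par) objgrad(par)$grad,
                  control = list(iter.max = 500, eval.max = 1000)),
    error = function(e) NULL)
  # nlminb occasionally reports false convergence at an exact optimum
  # (saturated models); a near-zero gradient counts as converged
  converged <- !is.null(opt) && opt$objective < 1e9 &&
    (opt$convergence == 0 ||
       max(abs(objgrad(opt$par)$grad)) < 1e-5)
  if (is.null(opt)) {
    pp <- .ml_unpack(start, p, spec, lay)
    Fval <- NA_real_
  } else {
    pp <- .ml_unpack(opt$par, p, spec, lay)
    Fval <- max(opt$objective, 0)
  }
  Sigma <- .ml_sigma(pp)
  df <- p * (p + 1) / 2 - lay$n_par
  factor_cor <- if (lay$est_cov)
    pp$psi[1, 2] / sqrt(pp$psi[1, 1] * pp$psi[2, 2]) else NA_real_
  std_load <- pp$lambda %*% diag(sqrt(diag(pp$psi)), lay$nf) / sqrt(diag(Sigma))
  structure(list(
    estimator = "ML", method = "ml",
    estimates = list(lambda = pp$lambda, psi = pp$psi, theta = pp$theta,
                     factor_cor = factor_cor, std_loadings = std_load),
    F = Fval, T = n * Fval, T_unadjusted = n * Fval,
    df = df, scaling_factor = 1, shift = 0,
    converged = converged, heywood = any(pp$theta < 1e-4),
    sample_matrix = S, implied_matrix = Sigma, n = n,
    spec = spec, layout = lay, par = if (is.null(opt)) start else opt$par
  ), class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> %s  T=%.3f df=%d %s\n", x$estimator, x$T, x$df,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

# duplication matrix: vec(A) = D %*% vech(A) for symmetric p x p A
.duplication <- function(p) {
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  m <- 0
  for (j in seq_len(p)) for (i in j:p) {
    m <- m + 1
    D[(j - 1) * p + i, m] <- 1
    D[(i - 1) * p + j, m] <- 1
  }
  D
}

.vech <- function(A) A[lower.tri(A, diag = TRUE)]

# fourth-moment (divisor-N) asymptotic covariance of sqrt(N) vech(S)
.gamma_adf <- function(X) {
  n <- nrow(X)
  Z <- sweep(X, 2, colMeans(X))
  p <- ncol(X)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  W <- Z[, idx[, 1], drop = FALSE] * Z[, idx[, 2], drop = FALSE]
  W <- sweep(W, 2, colMeans(W))
  crossprod(W) / n
}

# numeric Jacobian of vech(Sigma(theta)) at the solution
.ml_delta <- function(fit) {
  p <- nrow(fit$sample_matrix)
  par <- fit$par
  h <- 1e-6
  sig <- function(par) .vech(.ml_sigma(.ml_unpack(par, p, fit$spec, fit$layout)))
  J <- vapply(seq_along(par), function(m) {
    pp <- par; pm <- par
    pp[m] <- pp[m] + h; pm[m] <- pm[m] - h
    (sig(pp) - sig(pm)) / (2 * h)
  }, numeric(p * (p + 1) / 2))
  J
}

# Satorra-Bentler scaling factor c = tr(U Gamma) / df for an ML fit
.sb_scaling <- function(Sigma, Delta, Gamma, df) {
  p <- nrow(Sigma)
  D <- .duplication(p)
  Sinv <- solve(Sigma)
  W <- 0.5 * t(D) %*% (Sinv %x% Sinv) %*% D
  U <- if (length(Delta) && ncol(Delta) > 0) {
    WD <- W %*% Delta
    W - WD %*% solve(t(Delta) %*% WD, t(WD))
  } else W
  sum(U * t(Gamma)) / df
}

#' Robust (MLR) correction of an ML fit
#'
#' Computes the Satorra-Bentler type mean-scaled statistic
#' `T_MLR = T_ML / c` with `c = tr(U Gamma) / df`, where `Gamma` is the
#' fourth-moment asymptotic covariance of the sample covariances and `U` the
#' normal-theory residual weight matrix evaluated at the ML solution.
#' Parameter estimates and SRMR are unchanged by the correction.
#'
#' @param fit A converged [fit_ml()] result.
#' @param data The dataset the fit was computed from.
#' @return A `cfa_fit` with estimator `"MLR"`, adjusted `T` and recorded
#'   `scaling_factor`; returned unchanged (with a warning) when `df = 0`.
#' @export
robustify_mlr <- function(fit, data) {
  stopifnot(inherits(fit, "cfa_fit"), fit$method %in% c("ml", "ml_baseline"))
  if (!fit$converged) return(fit)
  if (fit$df == 0) {
    warning("df = 0: robust scaling undefined, returning fit unchanged")
    return(fit)
  }
  X <- if (inherits(data, "ordinal_dataset")) data$values else data
  X <- matrix(as.numeric(X), nrow(X), ncol(X))
  Gamma <- .gamma_adf(X)
  Delta <- if (fit$method == "ml") .ml_delta(fit) else fit$delta
  c_sc <- .sb_scaling(fit$implied_matrix, Delta, Gamma, fit$df)
  fit$estimator <- "MLR"
  fit$scaling_factor <- c_sc
  fit$T <- fit$T_unadjusted / c_sc
  fit
}

# independence baseline for ML/MLR: free variances, zero covariances
.fit_ml_baseline <- function(data) {
  X <- if (inherits(data, "ordinal_dataset")) data$values else data
  X <- matrix(as.numeric(X), nrow(X), ncol(X))
  n <- nrow(X); p <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n
  Sigma <- diag(diag(S), p)
  Fval <- sum(log(diag(S))) - as.numeric(determinant(S)$modulus)
  df <- p * (p - 1) / 2
  # Jacobian of vech(Sigma) in the p free variances
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Delta <- matrix(0, nrow(idx), p)
  diag_rows <- which(idx[, 1] == idx[, 2])
  Delta[cbind(diag_rows, idx[diag_rows, 1])] <- 1
  structure(list(
    estimator = "ML", method = "ml_baseline",
    estimates = list(variances = diag(S)),
    F = Fval, T = n * Fval, T_unadjusted = n * Fval, df = df,
    scaling_factor = 1, shift = 0, converged = TRUE, heywood = FALSE,
    sample_matrix = S, implied_matrix = Sigma, n = n, delta = Delta
  ), class = "cfa_fit")
}
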