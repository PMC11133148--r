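# Diagonally weighted least squares on polychoric correlations, with the
# mean-and-variance adjusted (scaled-and-shifted, df-preserving) WLSMV
# statistic. Theta parameterization: residual variances of the latent
# response variables are fixed at 1, the first loading per factor at 1;
# thresholds are saturated, so only the correlation structure is fitted:
#   F = (s - sigma(theta))' diag(Gamma)^-1 (s - sigma(theta)),  T = N * F.

.cat_layout <- function(p, spec) {
  nf <- spec$n_factors
  first <- vapply(seq_len(nf), function(f) which(spec$assignment == f)[1],
                  integer(1))
  free_load <- which(!seq_len(p) %in% first)
  est_cov <- spec$correlation_mode == "estimated"
  list(nf = nf, first = first, free_load = free_load, est_cov = est_cov,
       n_par = length(free_load) + nf + as.integer(est_cov),
       idx_load = seq_along(free_load),
       idx_psi = length(free_load) + seq_len(nf),
       idx_cov = if (est_cov) length(free_load) + nf + 1L else integer(0))
}

.cat_unpack <- function(par, p, spec, lay) {
  lambda <- matrix(0, p, lay$nf)
  lambda[cbind(lay$first, seq_len(lay$nf))] <- 1
  lambda[cbind(lay$free_load, spec$assignment[lay$free_load])] <-
    par[lay$idx_load]
  psi <- diag(exp(par[lay$idx_psi]), lay$nf)
  if (lay$est_cov) psi[1, 2] <- psi[2, 1] <- par[lay$idx_cov]
  list(lambda = lambda, psi = psi)
}

# model-implied polychoric correlation vector (theta parameterization)
.cat_sigma_vec <- function(pp, pairs) {
  Sigma_star <- pp$lambda %*% pp$psi %*% t(pp$lambda) + diag(nrow(pp$lambda))
  d <- sqrt(diag(Sigma_star))
  P <- Sigma_star / outer(d, d)
  P[pairs]
}

#' Fit a CFA model to polychoric correlations (DWLS / WLSMV)
#'
#' DWLS minimizes the diagonally weighted least-squares discrepancy between
#' the sample polychoric correlations and the model-implied correlations and
#' reports the unadjusted statistic; WLSMV uses the same estimates but
#' applies the mean-and-variance adjusted (scaled-and-shifted) correction
#' computed from the full asymptotic covariance of the polychorics,
#' populating `scaling_factor` and `shift` so that
#' `T_adjusted = T / scaling_factor + shift`.
#'
#' @param data An `ordinal_dataset` (used when `polychorics` is missing).
#' @param spec Analysis model from [analysis_model_spec()].
#' @param variant `"DWLS"` or `"WLSMV"`.
#' @param polychorics Optional precomputed [estimate_polychorics()] summary
#'   (with `acov = "full"` for WLSMV).
#' @return A `cfa_fit`; `sample_matrix` and `implied_matrix` are correlation
#'   matrices.
#' @export
fit_categorical <- function(data, spec, variant = c("DWLS", "WLSMV"),
                            polychorics = NULL) {
  variant <- match.arg(variant)
  if (is.null(polychorics))
    polychorics <- estimate_polychorics(
      data, acov = if (variant == "WLSMV") "full" else "diag")
  ps <- polychorics
  p <- nrow(ps$rho)
  n <- ps$n
  pairs <- ps$pairs
  s <- ps$s
  w <- if (is.matrix(ps$gamma)) diag(ps$gamma) else ps$gamma
  if (is.null(w)) stop("polychorics must carry an asymptotic covariance ",
                       "(acov = 'diag' or 'full')", call. = FALSE)
  if (any(w <= 0)) stop("non-positive DWLS weight encountered", call. = FALSE)
  if (variant == "WLSMV" && !is.matrix(ps$gamma))
    stop("WLSMV needs the full asymptotic covariance (acov = 'full')",
         call. = FALSE)
  lay <- .cat_layout(p, spec)

  obj <- function(par) {
    pp <- .cat_unpack(par, p, spec, lay)
    if (lay$est_cov &&
        abs(pp$psi[1, 2]) >= sqrt(pp$psi[1, 1] * pp$psi[2, 2]))
      return(1e10)
    r <- s - .cat_sigma_vec(pp, pairs)
    sum(r * r / w)
  }

  start <- numeric(lay$n_par)
  start[lay$idx_load] <- 1
  for (f in seq_len(lay$nf)) {
    members <- which(spec$assignment == f)
    offd <- ps$rho[members, members][upper.tri(diag(length(members)))]
    start[lay$idx_psi[f]] <- log(min(max(mean(offd), 0.02), 0.95))
  }
  if (lay$est_cov) start[lay$idx_cov] <- 0

  opt <- tryCatch(
    stats::nlminb(start, obj, control = list(iter.max = 500, eval.max = 1000)),
    error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0 && opt$objective < 1e9
  par <- if (is.null(opt)) start else opt$par
  pp <- .cat_unpack(par, p, spec, lay)
  Fval <- if (is.null(opt)) NA_real_ else max(opt$objective, 0)
  Tstat <- n * Fval
  df <- nrow(pairs) - lay$n_par

  scaling <- 1; shift <- 0; T_report <- Tstat
  if (variant == "WLSMV" && converged && df > 0) {
    Delta <- .cat_delta(par, p, spec, lay, pairs)
    adj <- .mv_adjust(w, Delta, ps$gamma, df)
    scaling <- adj$scaling; shift <- adj$shift
    T_report <- Tstat / scaling + shift
  }

  Sigma_star <- pp$lambda %*% pp$psi %*% t(pp$lambda) + diag(p)
  d <- sqrt(diag(Sigma_star))
  P_imp <- Sigma_star / outer(d, d)
  factor_cor <- if (lay$est_cov)
    pp$psi[1, 2] / sqrt(pp$psi[1, 1] * pp$psi[2, 2]) else NA_real_
  std_load <- pp$lambda %*% diag(sqrt(diag(pp$psi)), lay$nf) / d
  structure(list(
    estimator = variant, method = "cat",
    estimates = list(lambda = pp$lambda, psi = pp$psi,
                     factor_cor = factor_cor, std_loadings = std_load),
    F = Fval, T = T_report, T_unadjusted = Tstat, df = df,
    scaling_factor = scaling, shift = shift,
    converged = converged, heywood = FALSE,
    sample_matrix = ps$rho, implied_matrix = P_imp, n = n,
    spec = spec, layout = lay, par = par, polychorics = ps
  ), class = "cfa_fit")
}

# numeric Jacobian of sigma(theta) for the correlation structure
.cat_delta <- function(par, p, spec, lay, pairs) {
  h <- 1e-6
  f <- function(par) .cat_sigma_vec(.cat_unpack(par, p, spec, lay), pairs)
  vapply(seq_along(par), function(m) {
    pp <- par; pm <- par
    pp[m] <- pp[m] + h; pm[m] <- pm[m] - h
    (f(pp) - f(pm)) / (2 * h)
  }, numeric(nrow(pairs)))
}

# mean-and-variance (scaled-and-shifted, df-preserving) adjustment:
#   a = sqrt(df / tr((U Gamma)^2)),  b = df - a tr(U Gamma),  T* = a T + b
.mv_adjust <- function(w, Delta, Gamma, df) {
  Winv <- diag(1 / w)
  U <- if (length(Delta) && ncol(Delta) > 0) {
    WD <- Winv %*% Delta
    Winv - WD %*% solve(t(Delta) %*% WD, t(WD))
  } else Winv
  M <- U %*% Gamma
  tr1 <- sum(diag(M))
  tr2 <- sum(M * t(M))
  a <- sqrt(df / tr2)
  list(scaling = 1 / a, shift = df - a * tr1, tr1 = tr1, tr2 = tr2)
}

#' Independence baseline model
#'
#' ML/MLR: free variances and zero covariances; DWLS/WLSMV: saturated
#' thresholds and zero polychoric correlations. The statistic variant
#' matches the estimator (robust-scaled for MLR, mean-and-variance adjusted
#' for WLSMV), and `df = p (p - 1) / 2` throughout.
#'
#' @param data The dataset the target model was fitted to.
#' @param estimator One of `"ML"`, `"MLR"`, `"DWLS"`, `"WLSMV"`.
#' @param polychorics Precomputed polychoric summary (categorical
#'   estimators); computed from `data` when missing.
#' @return A `cfa_fit`.
#' @export
fit_baseline <- function(data, estimator = c("ML", "MLR", "DWLS", "WLSMV"),
                         polychorics = NULL) {
  estimator <- match.arg(estimator)
  if (estimator %in% c("ML", "MLR")) {
    fit <- .fit_ml_baseline(data)
    if (estimator == "MLR") fit <- robustify_mlr(fit, data)
    return(fit)
  }
  if (is.null(polychorics))
    polychorics <- estimate_polychorics(
      data, acov = if (estimator == "WLSMV") "full" else "diag")
  ps <- polychorics
  w <- if (is.matrix(ps$gamma)) diag(ps$gamma) else ps$gamma
  Fval <- sum(ps$s^2 / w)
  Tstat <- ps$n * Fval
  df <- nrow(ps$pairs)
  scaling <- 1; shift <- 0; T_report <- Tstat
  if (estimator == "WLSMV") {
    adj <- .mv_adjust(w, matrix(0, df, 0), ps$gamma, df)
    scaling <- adj$scaling; shift <- adj$shift
    T_report <- Tstat / scaling + shift
  }
  p <- nrow(ps$rho)
  structure(list(
    estimator = estimator, method = "cat_baseline", estimates = list(),
    F = Fval, T = T_report, T_unadjusted = Tstat, df = df,
    scaling_factor = scaling, shift = shift, converged = TRUE,
    heywood = FALSE, sample_matrix = ps$rho, implied_matrix = diag(p),
    n = ps$n
  ), class = "cfa_fit")
}
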