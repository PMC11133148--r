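#' Comparative fit index
#'
#' `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`, with value 1
#' when the denominator is zero.
#'
#' @param T,df Target-model statistic and degrees of freedom.
#' @param T_b,df_b Baseline (independence) statistic and degrees of freedom.
#' @return CFI in `[0, 1]`.
#' @export
compute_cfi <- function(T, df, T_b, df_b) {
  num <- max(T - df, 0)
  den <- max(T_b - df_b, T - df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Root mean square error of approximation
#'
#' `RMSEA = sqrt(max(T - df, 0) / (df * N))`; `NA` when `df = 0`.
#'
#' @param T Test statistic.
#' @param df Degrees of freedom.
#' @param n Sample size.
#' @export
compute_rmsea <- function(T, df, n) {
  if (df == 0) return(NA_real_)
  sqrt(max(T - df, 0) / (df * n))
}

#' Standardized root mean square residual
#'
#' Root of the mean squared standardized residual over the lower triangle
#' including the diagonal (`p (p + 1) / 2` elements). For covariance input
#' residuals are standardized by the sample standard deviations; for
#' correlation input (categorical estimators) the diagonal residuals are
#' zero by construction but still counted.
#'
#' @param sample_matrix,implied_matrix Conformable symmetric moment
#'   matrices.
#' @param scale Per-variable standard deviations; defaults to the square
#'   root of the sample diagonal.
#' @export
compute_srmr <- function(sample_matrix, implied_matrix, scale = NULL) {
  stopifnot(all(dim(sample_matrix) == dim(implied_matrix)))
  if (is.null(scale)) scale <- sqrt(diag(sample_matrix))
  if (any(scale <= 0)) stop("zero scale in SRMR standardization", call. = FALSE)
  R <- (sample_matrix - implied_matrix) / outer(scale, scale)
  sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
}

#' Assemble the five fit indices for one replication
#'
#' Uses each estimator's reported statistic (the robust-scaled or
#' mean-and-variance adjusted statistic for MLR/WLSMV, in both the target
#' and the baseline model). SRMR is computed from the sample and implied
#' moment matrices and is therefore identical under ML/MLR and under
#' DWLS/WLSMV.
#'
#' @param fit Target-model `cfa_fit`.
#' @param baseline Matching [fit_baseline()] result.
#' @param n Sample size (defaults to the fit's).
#' @return One-row data frame: `chi2`, `df`, `chi2_df`, `cfi`, `rmsea`,
#'   `srmr`, `scaling_factor`, `shift`, `factor_cor`, `converged`,
#'   `heywood`.
#' @export
gof_record <- function(fit, baseline, n = fit$n) {
  stopifnot(inherits(fit, "cfa_fit"), inherits(baseline, "cfa_fit"))
  if (fit$estimator != baseline$estimator)
    stop("target and baseline must use the same estimator", call. = FALSE)
  conv <- fit$converged && baseline$converged
  if (!conv) {
    return(data.frame(chi2 = NA_real_, df = fit$df, chi2_df = NA_real_,
                      cfi = NA_real_, rmsea = NA_real_, srmr = NA_real_,
                      scaling_factor = NA_real_, shift = NA_real_,
                      factor_cor = NA_real_, converged = FALSE,
                      heywood = fit$heywood))
  }
  T <- fit$T; df <- fit$df
  data.frame(
    chi2 = T, df = df,
    chi2_df = if (df > 0) T / df else NA_real_,
    cfi = compute_cfi(T, df, baseline$T, baseline$df),
    rmsea = compute_rmsea(T, df, n),
    srmr = compute_srmr(fit$sample_matrix, fit$implied_matrix),
    scaling_factor = fit$scaling_factor, shift = fit$shift,
    factor_cor = fit$estimates$factor_cor %||% NA_real_,
    converged = TRUE, heywood = fit$heywood)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
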