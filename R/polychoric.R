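#' Two-step polychoric correlations with asymptotic covariance
#'
#' Thresholds are estimated from the univariate margins
#' (`qnorm` of cumulative proportions); each pairwise correlation then
#' maximizes the bivariate-normal likelihood of the pair's contingency table
#' with thresholds held fixed. The asymptotic covariance `gamma` of
#' `sqrt(n) * (rho_hat - rho)` accounts for the two-step estimation through
#' the stacked estimating equations of thresholds and correlations
#' (sandwich form: the threshold equations are the centered cumulative
#' indicators, the correlation equations the bivariate-likelihood scores).
#'
#' @param data An `ordinal_dataset` or integer matrix of codes `1..K`.
#' @param acov `"full"` (pair-by-pair covariance matrix of all correlations,
#'   needed for the mean-and-variance adjusted test statistic), `"diag"`
#'   (variances only, enough for DWLS weights), or `"none"`.
#' @param n_options Category count when `data` is a bare matrix.
#' @return Object of class `polychoric_summary`: `thresholds` (list per
#'   column), `rho` (p x p correlation matrix), `pairs` (2-column index
#'   matrix in the order used by the `s` vector), `s` (vector of pairwise
#'   correlations), `gamma` (matrix, vector, or `NULL`), `n`, and
#'   `boundary` (flag per pair for estimates at the search boundary).
#' @export
estimate_polychorics <- function(data, acov = c("full", "diag", "none"),
                                 n_options = NULL) {
  acov <- match.arg(acov)
  X <- if (inherits(data, "ordinal_dataset")) data$values else data
  K <- if (inherits(data, "ordinal_dataset")) data$n_options
       else if (is.null(n_options)) max(X) else as.integer(n_options)
  n <- nrow(X)
  p <- ncol(X)
  counts <- apply(X, 2, tabulate, nbins = K)
  if (any(colSums(counts > 0) < 2))
    stop("every column needs at least 2 observed categories", call. = FALSE)

  # step 1: thresholds from margins (only between observed extreme categories)
  taus <- lapply(seq_len(p), function(j) {
    cum <- cumsum(counts[, j])[-K] / n
    stats::qnorm(pmin(pmax(cum, 1e-12), 1 - 1e-12))
  })

  pairs <- t(utils::combn(p, 2))
  npair <- nrow(pairs)
  rho_vec <- numeric(npair)
  boundary <- logical(npair)
  tables <- vector("list", npair)
  bound <- 0.999
  for (m in seq_len(npair)) {
    j <- pairs[m, 1]; k <- pairs[m, 2]
    tab <- table(factor(X[, j], levels = 1:K), factor(X[, k], levels = 1:K))
    tables[[m]] <- tab <- matrix(as.numeric(tab), K, K)
    nll <- function(r) {
      P <- bvn_cell_probs(taus[[j]], taus[[k]], r)
      -sum(tab * log(pmax(P, 1e-300)))
    }
    opt <- stats::optimize(nll, c(-bound, bound), tol = 1e-8)
    rho_vec[m] <- opt$minimum
    boundary[m] <- abs(opt$minimum) > bound - 1e-4
  }
  rho <- diag(p)
  rho[pairs] <- rho_vec
  rho[pairs[, 2:1, drop = FALSE]] <- rho_vec

  gamma <- NULL
  if (acov != "none") {
    gamma <- .polychoric_gamma(X, K, taus, pairs, rho_vec, tables, counts)
    if (acov == "diag") gamma <- diag(gamma)
  }
  structure(list(thresholds = taus, rho = rho, pairs = pairs, s = rho_vec,
                 gamma = gamma, n = n, n_options = K, boundary = boundary),
            class = "polychoric_summary")
}

#' @export
print.polychoric_summary <- function(x, ...) {
  cat(sprintf("<polychoric_summary> p=%d, n=%d, K=%d\n",
              nrow(x$rho), x$n, x$n_options))
  invisible(x)
}

# score table d log pi_ab / d rho over the K x K cells
.poly_score_table <- function(tau1, tau2, rho) {
  P <- pmax(bvn_cell_probs(tau1, tau2, rho), 1e-300)
  bvn_cell_dprobs(tau1, tau2, rho) / P
}

# sandwich asymptotic covariance of sqrt(n)(rho_hat - rho), rho block.
# Estimating equations, per observation i:
#   thresholds (col j, level a):  1{x_ij <= a} - pnorm(tau_ja)
#   correlations (pair j<k):      d log pi_{x_ij, x_ik} / d rho_jk
# A = d mean-equation / d params (thresholds block diagonal -phi(tau);
# correlation rows by central differences of the frequency-weighted mean
# score); B = empirical covariance of the stacked equations.
.polychoric_gamma <- function(X, K, taus, pairs, rho_vec, tables, counts) {
  n <- nrow(X); p <- ncol(X)
  npair <- nrow(pairs)
  nthr <- K - 1
  q <- p * nthr + npair
  thr_idx <- function(j) (j - 1) * nthr + seq_len(nthr)
  rho_idx <- p * nthr + seq_len(npair)

  # per-observation estimating equations
  Psi <- matrix(0, n, q)
  for (j in seq_len(p)) {
    ind <- outer(X[, j], seq_len(nthr), "<=")           # n x (K-1)
    Psi[, thr_idx(j)] <- sweep(ind, 2, stats::pnorm(taus[[j]]))
  }
  for (m in seq_len(npair)) {
    j <- pairs[m, 1]; k <- pairs[m, 2]
    S <- .poly_score_table(taus[[j]], taus[[k]], rho_vec[m])
    Psi[, rho_idx[m]] <- S[cbind(X[, j], X[, k])]
  }
  Psi <- sweep(Psi, 2, colMeans(Psi))
  B <- crossprod(Psi) / n

  A <- matrix(0, q, q)
  for (j in seq_len(p))
    A[cbind(thr_idx(j), thr_idx(j))] <- -stats::dnorm(taus[[j]])

  mean_score <- function(tab, tau1, tau2, rho)
    sum(tab * .poly_score_table(tau1, tau2, rho)) / n
  h <- 1e-5
  for (m in seq_len(npair)) {
    j <- pairs[m, 1]; k <- pairs[m, 2]
    tab <- tables[[m]]
    row <- rho_idx[m]
    for (a in seq_len(nthr)) {
      tp <- taus[[j]]; tp[a] <- tp[a] + h
      tm <- taus[[j]]; tm[a] <- tm[a] - h
      A[row, thr_idx(j)[a]] <- (mean_score(tab, tp, taus[[k]], rho_vec[m]) -
                                  mean_score(tab, tm, taus[[k]], rho_vec[m])) / (2 * h)
      tp <- taus[[k]]; tp[a] <- tp[a] + h
      tm <- taus[[k]]; tm[a] <- tm[a] - h
      A[row, thr_idx(k)[a]] <- (mean_score(tab, taus[[j]], tp, rho_vec[m]) -
                                  mean_score(tab, taus[[j]], tm, rho_vec[m])) / (2 * h)
    }
    A[row, row] <- (mean_score(tab, taus[[j]], taus[[k]], rho_vec[m] + h) -
                      mean_score(tab, taus[[j]], taus[[k]], rho_vec[m] - h)) / (2 * h)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv)
  V[rho_idx, rho_idx, drop = FALSE]
}
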