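# Bivariate standard-normal CDF and density.
#
# pbvnorm() follows Genz's hybrid quadrature for the rectangle probability
# (Gauss-Legendre on the arcsine representation for moderate correlation, the
# transformed near-singular expansion for |rho| > 0.925). Vectorized over
# (h, k) pairs at a common rho, which is the access pattern of the polychoric
# likelihood (one correlation, a grid of cell corners).

# Gauss-Legendre nodes/weights on [-1, 1] via the Jacobi (Golub-Welsch) matrix
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}
.gl20 <- .gauss_legendre(20)

# P(X > dh, Y > dk) for standard bivariate normal, scalar r, vector dh/dk
.bvnd <- function(dh, dk, r) {
  twopi <- 2 * pi
  x <- .gl20$x; w <- .gl20$w
  if (abs(r) < 0.925) {
    hk <- dh * dk
    hs <- (dh * dh + dk * dk) / 2
    asr <- asin(r)
    sn <- sin(asr * (1 + x) / 2)
    a <- sn / (1 - sn * sn)
    b <- 1 / (1 - sn * sn)
    M <- exp(outer(hk, a) - outer(hs, b))
    bvn <- drop(M %*% w) * asr / (4 * pi)
    bvn + stats::pnorm(-dh) * stats::pnorm(-dk)
  } else {
    hk <- dh * dk
    if (r < 0) {
      dk <- -dk
      hk <- -hk
    }
    bvn <- numeric(length(dh))
    if (abs(r) < 1) {
      as_ <- (1 - r) * (1 + r)
      a <- sqrt(as_)
      bs <- (dh - dk)^2
      cc <- (4 - hk) / 8
      d <- (12 - hk) / 16
      asr <- -(bs / as_ + hk) / 2
      ok <- asr > -100
      bvn[ok] <- (a * exp(asr) * (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 +
                                    cc * d * as_^2 / 5))[ok]
      ok <- -hk < 100
      bsr <- sqrt(bs)
      bvn[ok] <- bvn[ok] - (exp(-hk / 2) * sqrt(twopi) *
                              stats::pnorm(-bsr / a) * bsr *
                              (1 - cc * bs * (1 - d * bs / 5) / 3))[ok]
      a2 <- a / 2
      for (j in seq_along(x)) {
        wi <- w[j]
        xs <- (a2 * (x[j] + 1))^2
        rs <- sqrt(1 - xs)
        asr <- -(bs / xs + hk) / 2
        ok <- asr > -100
        term <- a2 * wi * exp(asr) *
          (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs - (1 + cc * xs * (1 + d * xs)))
        bvn[ok] <- bvn[ok] + term[ok]
      }
      bvn <- -bvn / twopi
    }
    if (r > 0) {
      bvn + stats::pnorm(-pmax(dh, dk))
    } else {
      bvn <- -bvn
      ifelse(dk > dh, bvn + stats::pnorm(dk) - stats::pnorm(dh), bvn)
    }
  }
}

#' Bivariate standard-normal CDF
#'
#' `P(X <= h, Y <= k)` for a standard bivariate normal with correlation
#' `rho`; vectorized over `h` and `k` (recycled), scalar `rho`. Accurate to
#' about 1e-14 for `|rho| <= 0.999`.
#'
#' @param h,k Upper limits; `Inf`/`-Inf` allowed.
#' @param rho Correlation in (-1, 1).
#' @return Vector of probabilities.
#' @keywords internal
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(pmin(pmax(h, -8.5), 8.5), n)
  k <- rep_len(pmin(pmax(k, -8.5), 8.5), n)
  if (abs(rho) < 1e-14) return(stats::pnorm(h) * stats::pnorm(k))
  pmin(pmax(.bvnd(-h, -k, rho), 0), 1)
}

# bivariate normal density, 0 at infinite corners
dbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  out <- numeric(n)
  fin <- is.finite(h) & is.finite(k)
  om <- 1 - rho^2
  out[fin] <- exp(-(h[fin]^2 - 2 * rho * h[fin] * k[fin] + k[fin]^2) / (2 * om)) /
    (2 * pi * sqrt(om))
  out
}

# K1 x K2 cell probabilities from thresholds tau1, tau2 and correlation rho
bvn_cell_probs <- function(tau1, tau2, rho) {
  t1 <- c(-Inf, tau1, Inf)
  t2 <- c(-Inf, tau2, Inf)
  G <- matrix(pbvnorm(rep(t1, times = length(t2)),
                      rep(t2, each = length(t1)), rho),
              length(t1), length(t2))
  P <- G[-1, -1, drop = FALSE] - G[-nrow(G), -1, drop = FALSE] -
    G[-1, -ncol(G), drop = FALSE] + G[-nrow(G), -ncol(G), drop = FALSE]
  pmax(P, 0)
}

# d cell probs / d rho: signed corner differences of the bivariate density
bvn_cell_dprobs <- function(tau1, tau2, rho) {
  t1 <- c(-Inf, tau1, Inf)
  t2 <- c(-Inf, tau2, Inf)
  G <- matrix(dbvnorm(rep(t1, times = length(t2)),
                      rep(t2, each = length(t1)), rho),
              length(t1), length(t2))
  G[-1, -1, drop = FALSE] - G[-nrow(G), -1, drop = FALSE] -
    G[-1, -ncol(G), drop = FALSE] + G[-nrow(G), -ncol(G), drop = FALSE]
}
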