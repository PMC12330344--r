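#' Bivariate standard normal cdf
#'
#' Vectorized rectangle-probability backend used by every copula density in
#' the package, so the evaluation routine can be swapped in one place.
#' Absolute accuracy is about 1e-15.
#'
#' @param a,b upper integration limits.
#' @param rho correlation in (-1, 1).
#' @return `P(X <= a, Y <= b)` for standard bivariate normal `(X, Y)`.
#' @export
bvn_cdf <- function(a, b, rho) {
  n <- max(length(a), length(b), length(rho))
  .bvn_cdf_cpp(rep_len(as.numeric(a), n), rep_len(as.numeric(b), n),
               rep_len(as.numeric(rho), n))
}

.clip_unit <- function(F) pmin(pmax(F, 1e-15), 1 - 1e-15)

#' Gaussian-copula joint cdf with NBII margins
#'
#' `G(y1, y2) = Phi2(qnorm(F1(y1)), qnorm(F2(y2)); rho)`. Marginal cdf values
#' are clipped into `[1e-15, 1 - 1e-15]` before the normal quantile so counts
#' deep in the tails cannot produce infinities. Arguments of `-1` denote the
#' empty event and give 0.
#'
#' @param y1,y2 integer counts (`-1` allowed).
#' @param mu1,sigma1,mu2,sigma2 NBII marginal parameters.
#' @param rho copula correlation in (-1, 1).
#' @return vector of probabilities.
#' @export
copula_cdf <- function(y1, y2, mu1, sigma1, mu2, sigma2, rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  n <- max(length(y1), length(y2), length(mu1), length(sigma1),
           length(mu2), length(sigma2), length(rho))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n); rho <- rep_len(rho, n)
  F1 <- nb_cdf(y1, rep_len(mu1, n), rep_len(sigma1, n))
  F2 <- nb_cdf(y2, rep_len(mu2, n), rep_len(sigma2, n))
  out <- numeric(n)
  ok <- y1 >= 0 & y2 >= 0
  if (any(ok)) {
    out[ok] <- bvn_cdf(qnorm(.clip_unit(F1[ok])), qnorm(.clip_unit(F2[ok])),
                       rho[ok])
  }
  out
}

#' Joint pmf of the bivariate Gaussian copula with NBII margins
#'
#' Rectangle differencing of [copula_cdf]:
#' `g(y1,y2) = G(y1,y2) - G(y1-1,y2) - G(y1,y2-1) + G(y1-1,y2-1)`.
#' Floating-point residuals more negative than -1e-12 raise an error (they
#' would signal a defective cdf backend); smaller ones are clamped to 0.
#' At `rho = 0` the product of the marginal pmfs is returned exactly.
#'
#' @inheritParams copula_cdf
#' @param y1,y2 non-negative integer counts.
#' @return vector of probabilities.
#' @export
joint_pmf <- function(y1, y2, mu1, sigma1, mu2, sigma2, rho) {
  if (any(y1 < 0) || any(y2 < 0)) stop("counts must be non-negative")
  n <- max(length(y1), length(y2), length(mu1), length(sigma1),
           length(mu2), length(sigma2), length(rho))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  mu1 <- rep_len(mu1, n); sigma1 <- rep_len(sigma1, n)
  mu2 <- rep_len(mu2, n); sigma2 <- rep_len(sigma2, n)
  rho <- rep_len(rho, n)
  out <- numeric(n)
  ind <- rho == 0
  if (any(ind)) {
    out[ind] <- nb_pmf(y1[ind], mu1[ind], sigma1[ind]) *
      nb_pmf(y2[ind], mu2[ind], sigma2[ind])
  }
  if (any(!ind)) {
    k <- which(!ind)
    g <- copula_cdf(y1[k], y2[k], mu1[k], sigma1[k], mu2[k], sigma2[k], rho[k]) -
      copula_cdf(y1[k] - 1L, y2[k], mu1[k], sigma1[k], mu2[k], sigma2[k], rho[k]) -
      copula_cdf(y1[k], y2[k] - 1L, mu1[k], sigma1[k], mu2[k], sigma2[k], rho[k]) +
      copula_cdf(y1[k] - 1L, y2[k] - 1L, mu1[k], sigma1[k], mu2[k], sigma2[k], rho[k])
    if (any(g < -1e-12))
      stop("internal consistency error: rectangle probability below -1e-12")
    out[k] <- pmax(g, 0)
  }
  out
}

#' Zero-inflated joint pmf
#'
#' Four-branch dropout mixture over [joint_pmf]: independent Bernoulli
#' dropout events with probabilities `p1`, `p2` send the respective count to
#' zero, so zeros can arise either from the count model or from dropout.
#'
#' @inheritParams joint_pmf
#' @param p1,p2 dropout probabilities in `[0, 1]`.
#' @return vector of probabilities.
#' @export
zi_joint_pmf <- function(y1, y2, mu1, sigma1, mu2, sigma2, rho, p1, p2) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) stop("p must be in [0, 1]")
  n <- max(length(y1), length(y2), length(mu1), length(sigma1),
           length(mu2), length(sigma2), length(rho), length(p1), length(p2))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  mu1 <- rep_len(mu1, n); sigma1 <- rep_len(sigma1, n)
  mu2 <- rep_len(mu2, n); sigma2 <- rep_len(sigma2, n)
  rho <- rep_len(rho, n); p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  g <- joint_pmf(y1, y2, mu1, sigma1, mu2, sigma2, rho)
  q1 <- 1 - p1; q2 <- 1 - p2
  f <- q1 * q2 * g
  b2 <- y1 > 0 & y2 == 0
  if (any(b2)) {
    f[b2] <- f[b2] + q1[b2] * p2[b2] * nb_pmf(y1[b2], mu1[b2], sigma1[b2])
  }
  b3 <- y1 == 0 & y2 > 0
  if (any(b3)) {
    f[b3] <- f[b3] + p1[b3] * q2[b3] * nb_pmf(y2[b3], mu2[b3], sigma2[b3])
  }
  b4 <- y1 == 0 & y2 == 0
  if (any(b4)) {
    f[b4] <- f[b4] + p1[b4] * p2[b4] +
      q1[b4] * p2[b4] * nb_pmf(0L, mu1[b4], sigma1[b4]) +
      p1[b4] * q2[b4] * nb_pmf(0L, mu2[b4], sigma2[b4])
  }
  f
}

#' Zero-inflated negative binomial marginal pmf
#'
#' The marginal law implied by [zi_joint_pmf]: `p + (1 - p) f_NB(0)` at zero
#' and `(1 - p) f_NB(y)` for positive counts.
#'
#' @inheritParams nb_pmf
#' @param p dropout probability in `[0, 1]`.
#' @return vector of probabilities.
#' @export
zinb_marginal_pmf <- function(y, mu, sigma, p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  n <- max(length(y), length(mu), length(sigma), length(p))
  y <- rep_len(y, n); p <- rep_len(p, n)
  f <- (1 - p) * nb_pmf(y, rep_len(mu, n), rep_len(sigma, n))
  f[y == 0] <- f[y == 0] + p[y == 0]
  f
}
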