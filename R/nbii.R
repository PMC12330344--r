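#' NBII negative binomial probability mass function
#'
#' Negative binomial under the mean / over-dispersion (NBII) parameterization:
#' expectation `mu`, variance `mu + mu^2 * sigma`. This corresponds to the
#' classical size/probability form with size `r = 1/sigma` and success
#' probability `r / (r + mu)`, the unique mapping with that mean-variance
#' relationship. As `sigma -> 0` the distribution approaches Poisson(`mu`);
#' below `sigma = 1e-8` the Poisson limit is evaluated directly because the
#' size parameter would overflow.
#'
#' @param y vector of non-negative integer counts.
#' @param mu positive mean parameter.
#' @param sigma positive over-dispersion parameter.
#' @return vector of probabilities.
#' @export
nb_pmf <- function(y, mu, sigma) {
  .check_nb_args(y, mu, sigma)
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  pois <- sigma < 1e-8
  if (any(pois)) out[pois] <- dpois(y[pois], mu[pois])
  if (any(!pois)) {
    out[!pois] <- dnbinom(y[!pois], size = 1 / sigma[!pois], mu = mu[!pois])
  }
  out
}

#' NBII negative binomial cumulative distribution function
#'
#' `nb_cdf(-1, ...)` is 0 (the empty event), so rectangle differencing of the
#' copula cdf can treat `y - 1` uniformly.
#'
#' @inheritParams nb_pmf
#' @param y vector of integers, `-1` allowed.
#' @return vector of probabilities.
#' @export
nb_cdf <- function(y, mu, sigma) {
  .check_nb_args(y, mu, sigma, allow_minus1 = TRUE)
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  neg <- y < 0
  pois <- !neg & sigma < 1e-8
  rest <- !neg & !pois
  if (any(pois)) out[pois] <- ppois(y[pois], mu[pois])
  if (any(rest)) {
    out[rest] <- pnbinom(y[rest], size = 1 / sigma[rest], mu = mu[rest])
  }
  out
}

#' NBII negative binomial quantile function
#'
#' Smallest integer `y` with `nb_cdf(y) >= prob`. Probabilities at or above 1
#' are capped at the 1 - 1e-12 quantile with a warning.
#'
#' @param prob vector of probabilities in `[0, 1)`.
#' @inheritParams nb_pmf
#' @return vector of non-negative integers.
#' @export
nb_quantile <- function(prob, mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("mu and sigma must be positive")
  if (any(prob < 0)) stop("prob must be non-negative")
  if (any(prob >= 1)) {
    warning("prob >= 1 capped at the 1 - 1e-12 quantile")
    prob <- pmin(prob, 1 - 1e-12)
  }
  n <- max(length(prob), length(mu), length(sigma))
  prob <- rep_len(prob, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  pois <- sigma < 1e-8
  if (any(pois)) out[pois] <- qpois(prob[pois], mu[pois])
  if (any(!pois)) {
    out[!pois] <- qnbinom(prob[!pois], size = 1 / sigma[!pois], mu = mu[!pois])
  }
  out
}

.check_nb_args <- function(y, mu, sigma, allow_minus1 = FALSE) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be positive")
  if (any(y != floor(y))) stop("y must be integral")
  lo <- if (allow_minus1) -1L else 0L
  if (any(y < lo)) stop("y out of range")
  invisible(NULL)
}
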