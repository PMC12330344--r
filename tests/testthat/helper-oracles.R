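# shared oracles and fixtures, built in code

# central finite differences with one Richardson extrapolation step, so the
# oracle's own truncation error cannot mask implementation defects. The base
# steps sit in the stability plateau of the log-likelihood: much smaller
# steps are dominated by eps * |loglik| evaluation noise, much larger ones
# by truncation.
fd_gradient <- function(fn, x, h = 2e-4 * (1 + abs(x))) {
  d_at <- function(i, hi) {
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (fn(xp) - fn(xm)) / (2 * hi)
  }
  vapply(seq_along(x), function(i) {
    (4 * d_at(i, h[i] / 2) - d_at(i, h[i])) / 3
  }, numeric(1))
}

fd_hess_diag <- function(fn, x, h = 4e-4 * (1 + abs(x))) {
  f0 <- fn(x)
  d2_at <- function(i, hi) {
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (fn(xp) - 2 * f0 + fn(xm)) / hi^2
  }
  vapply(seq_along(x), function(i) {
    (4 * d2_at(i, h[i] / 2) - d2_at(i, h[i])) / 3
  }, numeric(1))
}

# NBII pmf from first principles (size r = 1/sigma, prob r/(r+mu))
nb_pmf_oracle <- function(y, mu, sigma) {
  r <- 1 / sigma
  q <- r / (r + mu)
  exp(lgamma(y + r) - lgamma(r) - lfactorial(y) + r * log(q) + y * log1p(-q))
}

# lambda-selection control small enough for simulation batteries
fast_control <- function(...) {
  fit_control(lambda_grid = 10^seq(-2, 4, by = 2), search = "climb",
              refine = FALSE, sweeps = 1, ...)
}

# decade-spaced grid: needed wherever standard errors (not just point
# estimates) are examined
se_control <- function(...) {
  fit_control(lambda_grid = 10^seq(-2, 4, by = 1), search = "climb",
              refine = FALSE, sweeps = 1, ...)
}

# small droplet-like dataset for fitter tests
small_pair <- function(seed = 42, m = 4, cells = 60, ...) {
  as_gene_pair_data(simulate_pair(droplet_preset(m = m,
                                                 cells_per_patient = cells,
                                                 ...),
                                  seed = seed))
}

# dataset for the derivative contract: low over-dispersion keeps every
# cell's joint density inside the range where the likelihood is evaluated
# to near machine precision, and substantial dropout keeps the dropout
# predictors far from their clip boundary (where the derivative is
# one-sided by construction); central-difference oracles are meaningful
# under both conditions
contract_pair <- function(seed) {
  small_pair(seed = seed, m = 3, cells = 10,
             alpha1 = c(-1.5, 0), alpha2 = c(-1.5, 0),
             p1 = c(0.15, 0.15), p2 = c(0.15, 0.15))
}

rand_cell_params <- function() {
  list(mu1 = exp(runif(1, 0, 3.5)), sigma1 = exp(runif(1, -2, 0.5)),
       mu2 = exp(runif(1, 0, 3.5)), sigma2 = exp(runif(1, -2, 0.5)),
       rho = runif(1, -0.9, 0.9),
       p1 = runif(1, 0.01, 0.4), p2 = runif(1, 0.01, 0.4))
}
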