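#' Control parameters for model fitting
#'
#' @param max_iter trust-region iteration cap per inner fit.
#' @param radius initial trust-region radius.
#' @param radius_max radius cap.
#' @param grad_tol first-order stop: terminate once the max-norm of the
#'   gradient falls below this (the epsilon-improvement rule also applies).
#' @param lambda_init smoothing value used for the first inner fit.
#' @param lambda_grid grid searched per variance component (coordinate-wise,
#'   warm-started). The default spans random-effect standard deviations from
#'   about 1e-3 to 100.
#' @param search `"grid"` evaluates the full grid per component; `"climb"`
#'   hill-climbs along the sorted grid from the component's current value
#'   (cheaper; relies on the per-coordinate AIC path being unimodal).
#' @param refine golden-section refinement of the selected grid point.
#' @param sweeps maximum coordinate sweeps over the variance components.
#' @param aic_tol stop sweeping when the AIC improves by less than this.
#' @param verbose print progress.
#' @return list of class `coexmix_control`.
#' @export
fit_control <- function(max_iter = 200, radius = 1, radius_max = 100,
                        grad_tol = 5e-6, lambda_init = 1,
                        lambda_grid = 10^seq(-4, 6, length.out = 11),
                        search = c("grid", "climb"),
                        refine = TRUE, sweeps = 2, aic_tol = 0.05,
                        verbose = FALSE) {
  search <- match.arg(search)
  structure(list(max_iter = max_iter, radius = radius, radius_max = radius_max,
                 grad_tol = grad_tol, lambda_init = lambda_init,
                 lambda_grid = lambda_grid, search = search,
                 refine = refine, sweeps = sweeps, aic_tol = aic_tol,
                 verbose = verbose), class = "coexmix_control")
}

.state_lambda <- function(blocks, state) {
  lam <- state$lambda
  if (length(blocks$comp_names) == 0) return(numeric(0))
  if (is.null(lam)) lam <- rep(0, length(blocks$comp_names))
  if (length(lam) == 1) lam <- rep(lam, length(blocks$comp_names))
  if (is.null(names(lam))) names(lam) <- blocks$comp_names
  lam
}

#' Penalized log-likelihood
#'
#' Sum over cells of the log zero-inflated joint pmf minus the ridge penalty
#' `0.5 * sum_theta u' diag(lambda) u`. Cell log-pmfs are floored at
#' `log(1e-300)` so isolated near-impossible counts cannot produce `-Inf`.
#'
#' @param data a [gene_pair_data].
#' @param blocks the matching [build_design] result.
#' @param state list with `delta`, `u` and `lambda` (one value per variance
#'   component; 0 or NULL means unpenalized).
#' @return scalar penalized log-likelihood.
#' @export
penalized_loglik <- function(data, blocks, state) {
  x <- .pack_state(blocks, state)
  pen <- .penalty_vector(blocks, .state_lambda(blocks, state))
  eta <- .eta_matrix(blocks, x)
  d <- .cell_derivs_cpp(data$y1, data$y2, eta, 0L)
  sum(d$ll) - 0.5 * sum(pen * x^2)
}

.gh_assemble <- function(blocks, d, x, pen) {
  P <- blocks$n_coef
  G <- numeric(P)
  H <- matrix(0, P, P)
  for (j in 1:7) {
    bj <- blocks$theta[[.THETA[j]]]
    if (!length(bj$idx)) next
    G[bj$idx] <- G[bj$idx] + as.vector(crossprod(bj$M, d$grad[, j]))
    for (k in j:7) {
      bk <- blocks$theta[[.THETA[k]]]
      if (!length(bk$idx)) next
      w <- d$hess[, (k - 1L) * k / 2L + j]
      B <- crossprod(bj$M * w, bk$M)
      H[bj$idx, bk$idx] <- H[bj$idx, bk$idx] + B
      if (k > j) H[bk$idx, bj$idx] <- H[bk$idx, bj$idx] + t(B)
    }
  }
  G <- G - pen * x
  H <- H - diag(pen, nrow = P)
  H <- (H + t(H)) / 2
  dimnames(H) <- list(blocks$coef_names, blocks$coef_names)
  names(G) <- blocks$coef_names
  list(grad = G, hess = H)
}

#' Gradient and Hessian of the penalized log-likelihood
#'
#' Per-cell derivatives with respect to the seven link-scale predictors are
#' computed by high-accuracy central differences in compiled code (with the
#' dropout terms handled analytically where they separate), then assembled to
#' the full coefficient vector through the design matrices by the chain rule.
#' Central finite differences on the full coefficient vector are the
#' correctness contract, enforced in the test suite.
#'
#' @inheritParams penalized_loglik
#' @return list with `grad` (named vector) and `hess` (symmetric matrix),
#'   both for the stacked coefficient vector `(delta, u)`.
#' @export
grad_hess <- function(data, blocks, state) {
  x <- .pack_state(blocks, state)
  pen <- .penalty_vector(blocks, .state_lambda(blocks, state))
  eta <- .eta_matrix(blocks, x)
  d <- .cell_derivs_cpp(data$y1, data$y2, eta, 2L)
  .gh_assemble(blocks, d, x, pen)
}

# --------------------------------------------------------------------------
# Trust-region maximization (More-Sorensen subproblem via eigendecomposition)
# --------------------------------------------------------------------------

.tr_subproblem <- function(g, H, radius) {
  eg <- eigen(H, symmetric = TRUE)
  lam <- eg$values
  Q <- eg$vectors
  gq <- as.vector(crossprod(Q, g))
  lmax <- max(lam)
  step_for <- function(nu) {
    dd <- nu - lam
    dd[dd < 1e-14] <- 1e-14
    as.vector(Q %*% (gq / dd))
  }
  if (lmax < -1e-12) {
    s <- step_for(0)
    if (sqrt(sum(s^2)) <= radius) {
      return(list(s = s, pred = sum(g * s) + 0.5 * sum(s * (H %*% s))))
    }
  }
  nu_lo <- max(0, lmax) + 1e-12
  norm_at <- function(nu) sqrt(sum((gq / pmax(nu - lam, 1e-14))^2))
  if (norm_at(nu_lo) < radius) {
    # hard case: gradient (numerically) orthogonal to the leading eigenvector
    s <- step_for(nu_lo)
    v <- Q[, which.max(lam)]
    rem <- radius^2 - sum(s^2)
    if (rem > 0) s <- s + sqrt(rem) * v
  } else {
    nu_hi <- nu_lo + 1
    while (norm_at(nu_hi) > radius) nu_hi <- nu_hi * 2 + 1
    root <- stats::uniroot(function(nu) 1 / norm_at(nu) - 1 / radius,
                           c(nu_lo, nu_hi), tol = 1e-10)
    s <- step_for(root$root)
  }
  list(s = s, pred = sum(g * s) + 0.5 * sum(s * (H %*% s)))
}

.trust_region <- function(x0, fn, gh, max_iter = 200, radius = 1,
                          radius_max = 100, grad_tol = 5e-6) {
  eps <- .Machine$double.eps
  x <- x0
  f <- fn(x)
  if (!is.finite(f)) stop("objective not finite at the starting values")
  converged <- FALSE
  iter <- 0L
  accepted <- 0L
  need_gh <- TRUE
  gh_stale <- FALSE
  g <- NULL; H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    if (need_gh) {
      d <- gh(x)
      g <- d$grad; H <- d$hess
      need_gh <- FALSE
      gh_stale <- FALSE
      if (max(abs(g)) < grad_tol) {
        converged <- TRUE
        break
      }
    }
    sub <- .tr_subproblem(g, H, radius)
    if (!is.finite(sub$pred) || sub$pred < eps) {
      converged <- TRUE
      break
    }
    f_new <- fn(x + sub$s)
    ared <- f_new - f
    ratio <- if (is.finite(f_new)) ared / sub$pred else -Inf
    hit_boundary <- sqrt(sum(sub$s^2)) >= 0.99 * radius
    if (is.finite(f_new) && ared > 0) {
      x <- x + sub$s
      f <- f_new
      accepted <- accepted + 1L
      need_gh <- TRUE
      gh_stale <- TRUE
      if (ared < eps) {
        converged <- TRUE
        break
      }
    }
    if (ratio < 0.25) {
      radius <- radius * 0.25
      if (radius < 1e-13) {
        converged <- TRUE
        break
      }
    } else if (ratio > 0.75 && hit_boundary) {
      radius <- min(radius * 2, radius_max)
    }
  }
  list(x = x, value = f, converged = converged, iterations = iter,
       accepted = accepted, grad = g, hess = H, gh_stale = gh_stale)
}

# --------------------------------------------------------------------------
# Starting values
# --------------------------------------------------------------------------

.start_logistic <- function(z, X, Z, w) {
  kf <- ncol(X); kr <- ncol(Z)
  if (kr > 0) {
    fit <- suppressWarnings(
      mgcv::gam(z ~ 0 + X + Z, family = binomial(), weights = w,
                paraPen = list(Z = list(diag(kr))))
    )
    co <- stats::coef(fit)
    kap <- co[seq_len(kf)]
    u <- co[kf + seq_len(kr)]
  } else {
    fit <- suppressWarnings(glm.fit(X, z, weights = w, family = binomial()))
    kap <- fit$coefficients
    u <- numeric(0)
  }
  kap[!is.finite(kap)] <- 0
  u[!is.finite(u)] <- 0
  list(kappa = pmin(pmax(kap, -15), 15), u = pmin(pmax(u, -15), 15))
}

.start_margin <- function(y, X, off, w) {
  fit <- suppressWarnings(glm.fit(X, y, weights = w, offset = off,
                                  family = poisson()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  mu_hat <- exp(pmin(as.vector(X %*% beta) + off, 30))
  sig <- sum(w * ((y - mu_hat)^2 - mu_hat)) / sum(w * mu_hat^2)
  sig <- min(max(sig, 1e-3), 1e3)
  list(beta = beta, sigma = sig, mu_hat = mu_hat)
}

#' Starting values for the penalized fit
#'
#' Dropout predictors are initialized from a weighted logistic regression of
#' the zero indicator on the parameter's own fixed and random design, with
#' weight 0.5 on zero observations and 1 on positive ones. Means come from a
#' weighted Poisson regression with the depth offset (so an intercept-only
#' fit reproduces the weighted moment estimate `sum(w y) / sum(w S)`),
#' over-dispersions from a weighted Pearson-type moment estimate, and the
#' correlation intercept from the `atanh` of the weighted correlation of
#' mid-probability normal scores. Random effects other than the dropout ones
#' start at zero.
#'
#' @inheritParams penalized_loglik
#' @return a state list with `delta` and `u` in packing order.
#' @export
starting_values <- function(data, blocks) {
  y1 <- data$y1; y2 <- data$y2
  if (all(y1 == 0) || all(y2 == 0)) stop("degenerate margin: gene has no counts")
  w1 <- ifelse(y1 == 0, 0.5, 1)
  w2 <- ifelse(y2 == 0, 0.5, 1)
  delta <- setNames(numeric(blocks$n_fixed),
                    blocks$coef_names[seq_len(blocks$n_fixed)])
  u <- setNames(numeric(blocks$n_coef - blocks$n_fixed),
                blocks$coef_names[setdiff(seq_len(blocks$n_coef),
                                          seq_len(blocks$n_fixed))])
  put_delta <- function(theta, vals) {
    nm <- blocks$theta[[theta]]$fixed_names
    vals <- vals[seq_len(min(length(vals), length(nm)))]
    delta[nm[seq_along(vals)]] <<- vals
  }
  # dropout
  for (j in 1:2) {
    t <- paste0("p", j)
    b <- blocks$theta[[t]]
    z <- as.numeric((if (j == 1) y1 else y2) == 0)
    w <- if (j == 1) w1 else w2
    st <- .start_logistic(z, b$X, b$Z, w)
    put_delta(t, st$kappa)
    if (length(st$u)) u[b$rand_names] <- st$u
  }
  # margins
  m1 <- .start_margin(y1, blocks$theta$mu1$X, blocks$theta$mu1$off, w1)
  m2 <- .start_margin(y2, blocks$theta$mu2$X, blocks$theta$mu2$off, w2)
  put_delta("mu1", m1$beta)
  put_delta("mu2", m2$beta)
  sig_start <- function(theta, sig) {
    nm <- blocks$theta[[theta]]$fixed_names
    ic <- grep(":\\(Intercept\\)$", nm)
    if (length(ic)) delta[nm[ic[1]]] <<- log(sig)
  }
  sig_start("sigma1", m1$sigma)
  sig_start("sigma2", m2$sigma)
  # correlation: weighted Pearson correlation of mid-probability normal scores
  mid_z <- function(y, mu, sig) {
    Fm <- nb_cdf(y - 1L, mu, sig) + 0.5 * nb_pmf(y, mu, sig)
    qnorm(.clip_unit(Fm))
  }
  z1 <- mid_z(y1, m1$mu_hat, m1$sigma)
  z2 <- mid_z(y2, m2$mu_hat, m2$sigma)
  w <- w1 * w2
  zb1 <- sum(w * z1) / sum(w); zb2 <- sum(w * z2) / sum(w)
  r <- sum(w * (z1 - zb1) * (z2 - zb2)) /
    sqrt(sum(w * (z1 - zb1)^2) * sum(w * (z2 - zb2)^2))
  if (!is.finite(r)) r <- 0
  nm_rho <- blocks$theta$rho$fixed_names
  ic <- grep(":\\(Intercept\\)$", nm_rho)
  if (length(ic)) delta[nm_rho[ic[1]]] <- atanh(min(max(r, -0.99), 0.99))
  list(delta = delta, u = u, lambda = NULL)
}

# --------------------------------------------------------------------------
# Inner fit at fixed lambda, and the nested fit with AIC-based selection
# --------------------------------------------------------------------------

.edf_from_hessians <- function(H_pen, pen) {
  H_unpen <- H_pen + diag(pen, nrow = nrow(H_pen))
  tr <- tryCatch(sum(diag(solve(H_pen, H_unpen))), error = function(e) NA_real_)
  if (!is.finite(tr)) {
    # ridge the penalized Hessian for inversion
    eg <- eigen(H_pen, symmetric = TRUE)
    vals <- pmin(eg$values, -1e-8)
    Hi <- eg$vectors %*% (t(eg$vectors) / vals)
    tr <- sum(diag(Hi %*% H_unpen))
  }
  tr
}

#' Maximize the penalized log-likelihood at fixed smoothing parameters
#'
#' Trust-region ascent with a quadratic model from [grad_hess]. Every
#' accepted step strictly increases the objective; the algorithm terminates
#' when an accepted step improves the objective or its quadratic model by
#' less than machine epsilon. Exceeding the iteration cap returns a result
#' flagged as non-converged, never an error.
#'
#' @inheritParams penalized_loglik
#' @param lambda named vector of smoothing parameters (one per variance
#'   component), or empty when the model has no random effects.
#' @param start state list (e.g. from [starting_values]).
#' @param control a [fit_control] list.
#' @return list with the optimum state, log-likelihoods, penalized Hessian,
#'   effective degrees of freedom and convergence diagnostics.
#' @export
fit_inner <- function(data, blocks, lambda, start, control = fit_control()) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  pen <- .penalty_vector(blocks, if (length(lambda)) lambda else numeric(0))
  x0 <- .pack_state(blocks, start)
  fn <- function(x) {
    eta <- .eta_matrix(blocks, x)
    sum(.cell_derivs_cpp(data$y1, data$y2, eta, 0L)$ll) - 0.5 * sum(pen * x^2)
  }
  gh <- function(x) {
    eta <- .eta_matrix(blocks, x)
    d <- .cell_derivs_cpp(data$y1, data$y2, eta, 2L)
    .gh_assemble(blocks, d, x, pen)
  }
  tr <- .trust_region(x0, fn, gh, max_iter = control$max_iter,
                      radius = control$radius,
                      radius_max = control$radius_max,
                      grad_tol = control$grad_tol)
  final <- if (tr$gh_stale || is.null(tr$grad)) gh(tr$x) else
    list(grad = tr$grad, hess = tr$hess)
  ll <- tr$value + 0.5 * sum(pen * tr$x^2)
  H <- final$hess
  edf <- .edf_from_hessians(H, pen)
  neg_def <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values) < 1e-6
  list(x = tr$x, state = .unpack_state(blocks, tr$x, lambda),
       loglik = ll, loglik_pen = tr$value,
       grad = final$grad, hessian = H, pen = pen,
       edf = edf, aic = -2 * ll + 2 * edf,
       converged = tr$converged, hessian_nd = neg_def,
       iterations = tr$iterations)
}

#' Fit the zero-inflated copula mixed model to a gene pair
#'
#' Nested optimization: an outer loop selects the smoothing parameters by
#' minimizing `AIC_eff = -2 loglik + 2 edf` with
#' `edf = trace(H_pen^-1 H_unpen)` at the inner optimum, via a warm-started
#' coordinate grid search (optionally refined by golden-section) on the log
#' scale; the inner loop is the trust-region ascent of [fit_inner].
#'
#' @param data a [gene_pair_data].
#' @param spec a [model_spec]; defaults to [pair_spec] on the spec's
#'   condition.
#' @param control a [fit_control].
#' @return object of class `coexmix_fit`.
#' @export
fit_pair <- function(data, spec = pair_spec(), control = fit_control()) {
  blocks <- build_design(data, spec)
  start <- starting_values(data, blocks)
  ncomp <- length(blocks$comp_names)
  n_inner <- 0L
  if (ncomp == 0) {
    inner <- fit_inner(data, blocks, numeric(0), start, control)
    n_inner <- 1L
  } else {
    lambda <- setNames(rep(control$lambda_init, ncomp), blocks$comp_names)
    # smoothing-parameter search runs at a looser first-order tolerance;
    # the final fit at the selected lambda uses the full tolerance
    sel_control <- control
    sel_control$grad_tol <- max(control$grad_tol, 5e-4)
    inner <- fit_inner(data, blocks, lambda, start, sel_control)
    n_inner <- 1L
    cur <- inner
    refit <- function(lam) {
      n_inner <<- n_inner + 1L
      fit_inner(data, blocks, lam, cur$state, sel_control)
    }
    grid <- sort(control$lambda_grid)
    # hill-climb along the (sorted) grid from the component's current value;
    # the AIC path in one lambda coordinate is in practice unimodal, so this
    # visits a few grid points instead of all of them
    climb_comp <- function(ci) {
      seen <- new.env(parent = emptyenv())
      get_fit <- function(ix) {
        key <- as.character(ix)
        if (is.null(seen[[key]])) {
          lam <- cur$state$lambda
          lam[ci] <- grid[ix]
          seen[[key]] <- refit(lam)
        }
        seen[[key]]
      }
      ix <- which.min(abs(log10(grid) - log10(cur$state$lambda[ci])))
      best <- get_fit(ix)
      repeat {
        moved <- FALSE
        for (d in c(1L, -1L)) {
          nx <- ix + d
          if (nx >= 1 && nx <= length(grid)) {
            cand <- get_fit(nx)
            if (is.finite(cand$aic) && cand$aic < best$aic) {
              ix <- nx
              best <- cand
              moved <- TRUE
              break
            }
          }
        }
        if (!moved) break
      }
      best
    }
    for (sweep in seq_len(control$sweeps)) {
      aic0 <- cur$aic
      for (ci in seq_len(ncomp)) {
        best <- cur
        if (identical(control$search, "climb")) {
          cand <- climb_comp(ci)
          if (is.finite(cand$aic) && cand$aic < best$aic) best <- cand
        } else {
          for (lv in grid) {
            lam <- cur$state$lambda
            lam[ci] <- lv
            cand <- refit(lam)
            if (is.finite(cand$aic) && cand$aic < best$aic) best <- cand
          }
        }
        if (control$refine) {
          l0 <- log10(best$state$lambda[ci])
          opt <- stats::optimize(function(lx) {
            lam <- best$state$lambda
            lam[ci] <- 10^lx
            cand <- refit(lam)
            if (is.finite(cand$aic) && cand$aic < best$aic) best <<- cand
            cand$aic
          }, interval = c(l0 - 1, l0 + 1), tol = 0.2)
        }
        cur <- best
        if (control$verbose)
          message(sprintf("  comp %s: lambda = %.3g, AIC = %.3f",
                          blocks$comp_names[ci], cur$state$lambda[ci], cur$aic))
      }
      if (aic0 - cur$aic < control$aic_tol) break
    }
    inner <- fit_inner(data, blocks, cur$state$lambda, cur$state, control)
    n_inner <- n_inner + 1L
  }
  cond <- blocks$condition
  tau1_name <- NA_character_
  if (!is.null(cond)) {
    cand <- grep(paste0("^rho:", cond), blocks$theta$rho$fixed_names,
                 value = TRUE)
    if (length(cand)) tau1_name <- cand[1]
  }
  out <- c(inner, list(blocks = blocks, genes = data$genes,
                       condition = cond, tau1_name = tau1_name,
                       n_inner_fits = n_inner,
                       control = control))
  class(out) <- "coexmix_fit"
  out
}

#' @exportS3Method base::print
print.coexmix_fit <- function(x, ...) {
  cat("coexmix fit:", paste(x$genes, collapse = " / "), "\n")
  cat("  log-likelihood", format(x$loglik, digits = 6),
      " edf", format(x$edf, digits = 4),
      " converged:", x$converged, "\n")
  if (!is.na(x$tau1_name)) {
    w <- wald(x, x$tau1_name)
    cat(sprintf("  %s = %.4f (SE %.4f, p = %.3g)\n", x$tau1_name,
                w$estimate, w$se, w$p))
  }
  invisible(x)
}
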