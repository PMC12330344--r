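.fit_vcov <- function(fit) {
  H <- fit$hessian
  eg <- eigen(-H, symmetric = TRUE)
  ev <- eg$values
  flat <- ev <= 1e-8
  # flat directions arise when a predictor is pinned at its clip boundary
  # (e.g. a dropout probability driven to 0 in a margin without excess
  # zeros); coefficients loading on them get flagged, the rest keep valid
  # Wald inference from the ridged inverse
  V <- eg$vectors %*% (t(eg$vectors) / pmax(ev, 1e-8))
  coef_singular <- if (any(flat))
    rowSums(eg$vectors[, flat, drop = FALSE]^2) > 1e-6
  else rep(FALSE, nrow(H))
  dimnames(V) <- dimnames(H)
  list(V = V, singular = any(flat), coef_singular = coef_singular)
}

#' Wald test for a fitted coefficient
#'
#' Standard error from the corresponding diagonal entry of the inverse
#' negative observed Hessian of the penalized log-likelihood; `z =
#' estimate/SE`, two-sided normal p-value, and a 95% confidence interval on
#' the link scale (symmetric about the estimate). Non-converged fits and
#' non-invertible Hessians are flagged; the latter propagate a missing
#' p-value.
#'
#' @param fit a `coexmix_fit`.
#' @param coefficient coefficient name (see `fit$blocks$coef_names`), e.g.
#'   `"rho:groupB"`; defaults to the differential co-expression contrast.
#' @return list of class `coexmix_test` with estimate, se, z, p, ci and
#'   flags.
#' @export
wald <- function(fit, coefficient = fit$tau1_name) {
  if (is.null(coefficient) || is.na(coefficient))
    stop("no coefficient given and the fit has no condition contrast")
  idx <- match(coefficient, fit$blocks$coef_names)
  if (is.na(idx)) stop("unknown coefficient: ", coefficient)
  vc <- .fit_vcov(fit)
  est <- unname(fit$x[idx])
  se <- sqrt(vc$V[idx, idx])
  singular <- vc$coef_singular[idx]
  flagged <- !isTRUE(fit$converged) || singular
  if (singular) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- est / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(coefficient = coefficient, estimate = est, se = se,
                 z = z, p = p,
                 ci = c(lower = est - 1.96 * se, upper = est + 1.96 * se),
                 converged = isTRUE(fit$converged), singular = singular,
                 flagged = flagged),
            class = "coexmix_test")
}

#' @exportS3Method base::print
print.coexmix_test <- function(x, ...) {
  cat(sprintf("%s: %.4f (SE %.4f), z = %.3f, p = %.4g, 95%% CI [%.4f, %.4f]%s\n",
              x$coefficient, x$estimate, x$se, x$z, x$p,
              x$ci[1], x$ci[2], if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Population-level correlation per condition group
#'
#' Group-wise copula correlations from the fitted fixed effects of the
#' `rho` predictor only (random-effect contributions excluded), i.e.
#' `rho_g = tanh(x_g' tau)`, plus the absolute difference used to rank gene
#' pairs.
#'
#' @param fit a `coexmix_fit` with a condition contrast.
#' @return list with `rho_group0`, `rho_group1` and `delta` (absolute
#'   difference).
#' @export
natural_scale_rho <- function(fit) {
  blocks <- fit$blocks
  cond <- fit$condition
  if (is.null(cond)) stop("fit has no condition covariate")
  b <- blocks$theta$rho
  tau <- fit$x[b$idx[seq_len(ncol(b$X))]]
  # the first cell of each condition level supplies the covariate pattern
  lev_rows <- blocks$cond_rows
  if (is.null(lev_rows)) stop("fit does not carry condition rows")
  rho_g <- vapply(lev_rows, function(i) tanh(sum(b$X[i, ] * tau)), numeric(1))
  list(rho_group0 = unname(rho_g[1]),
       rho_group1 = unname(rho_g[2]),
       delta = unname(abs(rho_g[2] - rho_g[1])))
}

#' Benjamini-Hochberg adjustment with missing-value pass-through
#'
#' Step-up BH adjustment (via [stats::p.adjust]) computed over the
#' non-missing p-values only, so flagged (non-converged) fits neither
#' receive an adjusted value nor dilute the correction.
#'
#' @param p vector of p-values in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, `NA` preserved.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
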