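---
title: "Modeling differential gene-gene co-expression with zero-inflated copula mixed models"
author: "coexmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling differential gene-gene co-expression with zero-inflated copula mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-cell RNA-seq experiments increasingly sample many cells from each of
several patients. A question that mean-level differential expression cannot
answer is whether the *dependence* between two genes changes across
conditions — pre- versus post-treatment, or one cell lineage versus another.
Testing this per gene pair faces three obstacles at once: counts are
over-dispersed and often zero-inflated; the association parameter itself may
depend on covariates; and cells from the same patient are correlated, so
treating them as independent inflates type I error.

`coexmix` addresses all three with a zero-inflated bivariate Gaussian-copula
regression in which every parameter carries its own linear predictor with
optional patient-level random effects.

## The model

For a cell $i$ with counts $(y_{i1}, y_{i2})$ of the two genes, each margin
is NBII negative binomial with mean $\mu_{ij}$ and over-dispersion
$\sigma_{ij}$ (variance $\mu + \mu^2\sigma$; size $1/\sigma$, success
probability $(1/\sigma)/(1/\sigma + \mu)$ — the unique size/probability
mapping with that moment structure; $\sigma \to 0$ recovers Poisson). The
joint cdf couples the margins through a bivariate standard normal with
correlation $\rho_i$:
$$G(y_1, y_2) = \Phi_2\!\left(\Phi^{-1}(F_{NB}(y_1)),\,
\Phi^{-1}(F_{NB}(y_2));\, \rho_i\right),$$
and the pre-dropout joint pmf is the rectangle difference
$g(y_1,y_2) = G(y_1,y_2) - G(y_1-1,y_2) - G(y_1,y_2-1) + G(y_1-1,y_2-1)$.
Independent Bernoulli dropout with probabilities $p_{i1}, p_{i2}$ mixes this
into four branches depending on which observed counts are zero; the implied
margins are zero-inflated negative binomials.

Each natural parameter is linked to a linear predictor:
$\log \mu_{ij} = x_i^\top\beta_j + z_i^\top u_{\mu_j} + \log S_i$ (with
$S_i$ the cell's total sequencing depth, computed over all genes before any
gene filtering), $\log \sigma_{ij}$, $\operatorname{atanh}\rho_i$ and
$\operatorname{logit} p_{ij}$ analogously but without the offset. The
coefficient of the condition indicator in the $\rho$ predictor — called
$\tau_1$ throughout — is the differential co-expression contrast: the null
hypothesis of no co-expression change is $\tau_1 = 0$.

Random intercepts $u_\theta$ are not integrated out: they are treated as
coefficients shrunk by a ridge penalty, so the objective is
$$\ell(\delta, u) = \sum_i \log f(y_{i1}, y_{i2}) -
\tfrac12 \sum_\theta u_\theta^\top \mathrm{diag}(\lambda_\theta)\, u_\theta .$$
All random coefficients in one variance component share a single smoothing
parameter $\lambda$; the implied random-effect variance is reported as
$1/\lambda$ (ridge $\leftrightarrow$ Gaussian prior of variance
$1/\lambda$ — a reporting convention, not an estimate of a free parameter).

## Fitting

**Inner loop.** For fixed $\lambda$, the penalized log-likelihood is
maximized by a trust-region Newton method. The quadratic subproblem is
solved through an eigendecomposition (Moré–Sorensen, with the hard case
handled); steps are accepted only when they strictly increase the
objective; the radius shrinks by 0.25 when the achieved/predicted
improvement ratio falls below 0.25 and doubles (capped at 100) when the
ratio exceeds 0.75 on a boundary step. Termination: an accepted step (or
its quadratic model) improves by less than machine epsilon, or the gradient
max-norm falls below `grad_tol` (default 5e-6). Exceeding `max_iter`
(default 200) returns a fit flagged non-converged rather than an error.

**Derivatives.** The gradient and Hessian are assembled by the chain rule
from per-cell derivatives with respect to the seven link-scale predictors.
Those per-cell derivatives are computed in compiled code by fourth-order
central stencils with step $4\times10^{-4}$; the dropout predictors, which
enter cells with two positive counts only through $\log(1-p_j)$, are
differentiated analytically there. The step size matters: the likelihood
is evaluated to roughly $10^{-15}$ absolute accuracy per bivariate-normal
rectangle, so second differences with much smaller steps amplify backend
micro-structure, while plain second-order differences with larger steps
suffer visible truncation where third derivatives are large. Fourth-order
stencils at $4\times10^{-4}$ avoid both; the test suite enforces agreement
with Richardson-extrapolated central differences on the full coefficient
vector (relative error below 1e-5 for the gradient, 1e-3 for the Hessian
diagonal).

**Outer loop.** The smoothing parameters minimize
$\mathrm{AIC}_{\mathrm{eff}} = -2\hat\ell + 2\,\mathrm{edf}$ with
$\mathrm{edf} = \mathrm{tr}(H_{\mathrm{pen}}^{-1} H_{\mathrm{unpen}})$
evaluated at the inner optimum — the standard penalized-likelihood
effective degrees of freedom. Selection is a warm-started coordinate grid
search on $\log_{10}\lambda$ (default grid $10^{-4}\ldots10^{6}$, 11
points, optional golden-section refinement, up to two sweeps). During the
search the inner fits run at a loosened first-order tolerance (1e-4); the
final fit at the selected $\lambda$ uses the full tolerance. The grid
search is a deliberate choice: it is derivative-free, reproducible, and
robust to the non-smoothness of the AIC path in $\lambda$, at the price of
more inner refits than a gradient-based update would need.

**Starting values.** Dropout predictors start from a weighted logistic
regression of the zero indicator on the parameter's own fixed and random
design (ridge on the random block via `mgcv::gam` with `paraPen`), with
weight 0.5 on zero observations and 1 on positive ones. The means start
from a weighted Poisson regression with the depth offset, so an
intercept-only model starts at $\sum w y / \sum w S$; over-dispersions from
a weighted Pearson-type moment estimate (floored at $10^{-3}$); the
correlation intercept from the atanh of the weighted correlation of
mid-probability normal scores; all other random effects start at zero.

## Inference

Standard errors come from the observed Hessian of the *penalized*
log-likelihood at the optimum — shrinkage makes intervals for the random
coefficients conservative, which we accept and document rather than
correct. Wald statistics, two-sided normal p-values, and 95% intervals
$\hat\theta \pm 1.96\,\mathrm{SE}$ are reported on the link scale.
Group-wise correlations are population-level: $\rho_g = \tanh(x_g^\top
\hat\tau)$ with the random-effect contribution excluded, and gene pairs are
ranked by $|\Delta\rho| = |\rho_{g1} - \rho_{g0}|$.

When a margin has no excess zeros the dropout predictor is driven to its
clip boundary ($\eta_p = -15$), leaving an exactly flat direction in the
Hessian. Rather than failing the whole fit, the covariance is computed from
a ridged eigendecomposition and only coefficients loading on flat
directions are flagged (missing p-value); the contrast of interest keeps
valid inference. Across gene pairs, Benjamini–Hochberg adjustment (via
`stats::p.adjust`) runs over the converged, unflagged fits only, so failed
fits neither receive adjusted values nor dilute the correction.

## The simulator

`simulate_pair()` generates data by the model's own mechanism: draw random
intercepts, build per-cell parameters through the links, draw a standard
bivariate normal pair with the cell's $\rho_i$, transform each coordinate
by the NBII quantile function, then apply Bernoulli dropout. Two presets
describe the two major scRNA-seq protocols: a droplet-like scenario
(depth $3\times10^4$, means $\approx 20$–$35$, over-dispersion
$\approx 0.6$, dropout 1–5%, $\tau = (0.06, -0.20)$) and a plate-like
scenario (depth $5\times10^5$, means $\approx 85$–$300$, over-dispersion
$\approx 1.7$–$3.2$, dropout 8–21%, $\tau = (0.35, -0.34)$). Dropout
levels are specified as natural-scale probabilities per condition group so
that "no zero-inflation" is expressible exactly; internally they become
logit-scale coefficients. Group assignment is a within-patient half/half
split for the droplet preset (a longitudinal pre/post design) and an
independent per-cell 50/50 split for the plate preset (two lineages within
each patient).

The published coefficient sets do not include random-effect variances; the
presets default to SD 0.2 for the mean and correlation intercepts and 0.1
for the dropout intercepts — large enough to make within-patient
correlation consequential, and overridable. A single seed drives
everything, with per-patient substreams derived deterministically so
changing the number of patients leaves shared patients' cells unchanged.

What the simulator does *not* emulate: ambient RNA, doublets, batch
effects, cell-to-cell depth variation (depth is constant at the protocol
mean), genome-scale gene-gene dependence structure, or any mechanism
outside the model family. Passing the recovery and calibration checks
below therefore demonstrates internal correctness of estimation and
inference under the model's own data-generating process, not robustness to
real-data misspecification.

## Validation sizes

The test suite exercises, among others: exactness of the joint pmf against
brute-force lattice sums and a $10^6$-draw Monte-Carlo oracle; the
finite-difference derivative contract; recovery of $\tau_1 = -0.20$ over
10 replicates of the droplet scenario at 10 patients × 250 cells; null
calibration over $B = 200$ replicates at 10 patients × 60 cells (exact
binomial band around 0.05, and Kolmogorov distance of the p-value ECDF
below 0.1); and interval coverage for $\tau_1$ over 20 replicates at 5
patients × 200 cells, with and without zero-inflation, against exact
binomial bands around the nominal rates. These sizes are the package's
validation choices; the simulation fits use the shared-component model
specification (`pair_spec()`), which matches the generator. Calibration
and coverage runs use a decade-spaced smoothing grid with the
hill-climbing search (`lambda_grid = 10^seq(-2, 4, by = 1)`,
`search = "climb"`, one sweep): a materially coarser grid misplaces
$\lambda$ by two orders of magnitude, which visibly distorts the standard
errors.

## Numerical choices

- Marginal cdf values are clipped into $[10^{-15}, 1 - 10^{-15}]$ before
  the normal quantile; linear predictors are clipped at $\pm 15$ (logit),
  $\pm 7$ (atanh), $\pm 12$ ($\log\sigma$), $\pm 30$ ($\log\mu$).
- Rectangle probabilities are computed by a compiled port of the standard
  Drezner–Wesolowsky/Genz bivariate-normal quadrature (absolute accuracy
  about $10^{-15}$); negative rectangle residuals above $-10^{-12}$ are
  clamped to zero, anything worse raises an internal-consistency error.
  All densities flow through this one backend.
- Differencing cdfs is only absolutely accurate, so a cell in the joint
  tail (rectangle probability below $10^{-6}$) would keep merely
  $\sim 10^{-15}/g$ relative accuracy — enough to corrupt derivative
  estimates. Such rectangles are recomputed by direct 20-point
  Gauss–Legendre quadrature of the bivariate normal density over the box,
  with the inner normal band evaluated through tail-accurate survival
  functions, restoring relative accuracy.
- Cell log-pmfs are floored at $\log(10^{-300})$ so single impossible-
  looking cells cannot destroy a fit.
- Below $\sigma = 10^{-8}$ the Poisson limit is evaluated directly (the
  negative binomial size parameter would overflow).
- Reproducibility under cell permutation is bounded by double precision:
  with $|\ell| \sim 10^3$ the optimizer cannot resolve objective
  differences below $\sim 10^{-13}$, capping iterate agreement near
  $10^{-7}$; the test suite asserts that bound.

## Limitations

Only the Gaussian copula is implemented (the interface keeps the copula
behind a single rectangle-probability function, so Archimedean families
are an extension point, not a supported feature). One random-effect
grouping factor per parameter; no smooth terms in predictors. Intervals
for random coefficients are conservative by construction. Dropout
parameters of margins without excess zeros pin at the clip boundary and
are reported as flagged rather than estimated. Screening fits each pair
independently; no information is shared across pairs beyond the BH
correction.
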