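test_that("penalized log-likelihood composes cell log-pmfs and the ridge penalty", {
  meta <- data.frame(cell_id = c("a", "b", "c"),
                     patient = c("p1", "p1", "p2"),
                     group = c("A", "B", "A"),
                     depth = c(1e4, 2e4, 3e4))
  gp <- gene_pair_data(c(3L, 0L, 5L), c(1L, 2L, 0L), meta)
  blocks <- build_design(gp, pair_spec())
  set.seed(9)
  st <- list(delta = rnorm(blocks$n_fixed, 0, 0.3),
             u = rnorm(blocks$n_coef - blocks$n_fixed, 0, 0.3),
             lambda = setNames(runif(length(blocks$comp_names), 0.5, 3),
                               blocks$comp_names))
  pp <- predict_params(blocks, st)
  hand <- sum(log(zi_joint_pmf(gp$y1, gp$y2, pp$mu1, pp$sigma1, pp$mu2,
                               pp$sigma2, pp$rho, pp$p1, pp$p2)))
  pen <- coexmix:::.penalty_vector(blocks, st$lambda)
  x <- coexmix:::.pack_state(blocks, st)
  expect_equal(penalized_loglik(gp, blocks, st),
               hand - 0.5 * sum(pen * x^2), tolerance = 1e-10)
  # lambda = 0 and u = 0 drop the penalty
  st0 <- st; st0$lambda <- st$lambda * 0
  expect_equal(penalized_loglik(gp, blocks, st0), hand, tolerance = 1e-10)
  stu <- st; stu$u[] <- 0
  ppu <- predict_params(blocks, stu)
  handu <- sum(log(zi_joint_pmf(gp$y1, gp$y2, ppu$mu1, ppu$sigma1, ppu$mu2,
                                ppu$sigma2, ppu$rho, ppu$p1, ppu$p2)))
  expect_equal(penalized_loglik(gp, blocks, stu), handu, tolerance = 1e-10)
})

test_that("gradient and Hessian honor the central finite-difference contract", {
  gp <- contract_pair(5)
  blocks <- build_design(gp, pair_spec())
  lam <- setNames(rep(1.5, length(blocks$comp_names)), blocks$comp_names)
  base <- starting_values(gp, blocks)
  set.seed(11)
  worst_g <- 0; worst_h <- 0
  for (rep in 1:20) {
    st <- list(delta = base$delta + rnorm(blocks$n_fixed, 0, 0.1),
               u = rnorm(blocks$n_coef - blocks$n_fixed, 0, 0.1),
               lambda = lam)
    x0 <- coexmix:::.pack_state(blocks, st)
    gh <- grad_hess(gp, blocks, st)
    fn <- function(x) penalized_loglik(
      gp, blocks, coexmix:::.unpack_state(blocks, x, lam))
    g_fd <- fd_gradient(fn, x0)
    h_fd <- fd_hess_diag(fn, x0)
    worst_g <- max(worst_g, max(abs(gh$grad - g_fd) / (1 + abs(g_fd))))
    worst_h <- max(worst_h, max(abs(diag(gh$hess) - h_fd) / (1 + abs(h_fd))))
    expect_equal(gh$hess, t(gh$hess))
  }
  expect_lt(worst_g, 1e-5)
  expect_lt(worst_h, 1e-3)
})

test_that("penalty contributes exactly -lambda * u to the gradient", {
  gp <- small_pair(seed = 6, m = 3, cells = 30)
  blocks <- build_design(gp, pair_spec())
  st <- starting_values(gp, blocks)
  st$u[] <- rnorm(length(st$u), 0, 0.4)
  st$lambda <- setNames(rep(2.5, length(blocks$comp_names)),
                        blocks$comp_names)
  st0 <- st; st0$lambda <- st$lambda * 0
  g1 <- grad_hess(gp, blocks, st)$grad
  g0 <- grad_hess(gp, blocks, st0)$grad
  x <- coexmix:::.pack_state(blocks, st)
  pen <- coexmix:::.penalty_vector(blocks, st$lambda)
  expect_equal(g1 - g0, -pen * x, tolerance = 1e-10)
})

test_that("trust region solves a quadratic toy exactly and obeys its radius rules", {
  B <- matrix(c(4, 1, 1, 3), 2)
  a <- c(1, -2)
  fn <- function(x) -0.5 * sum((x - a) * (B %*% (x - a)))
  gh <- function(x) list(grad = as.vector(-B %*% (x - a)), hess = -B)
  tr <- coexmix:::.trust_region(c(10, 10), fn, gh, max_iter = 50,
                                grad_tol = 1e-10)
  expect_true(tr$converged)
  expect_lt(max(abs(tr$x - a)), 1e-8)
  expect_lte(tr$iterations, 10)
  # ascent: the returned objective is at least the starting objective
  expect_gte(tr$value, fn(c(10, 10)))
})

test_that("starting values implement the weighted schemes", {
  # no zeros anywhere: weighted moment start is sum(y) / sum(S)
  meta <- data.frame(cell_id = sprintf("c%d", 1:40),
                     patient = rep("p1", 40),
                     depth = rep(c(1e4, 2e4), 20))
  set.seed(8)
  y1 <- rpois(40, 20) + 1L; y2 <- rpois(40, 30) + 1L
  gp <- gene_pair_data(y1, y2, meta)
  blocks <- build_design(gp, model_spec())
  st <- starting_values(gp, blocks)
  expect_equal(exp(unname(st$delta["mu1:(Intercept)"])),
               sum(y1) / sum(meta$depth), tolerance = 1e-6)
  # margins without zeros drive the dropout start to a clipped small value
  expect_lte(unname(st$delta["p1:(Intercept)"]), -5)
  expect_gte(unname(st$delta["p1:(Intercept)"]), -15)
  # single-patient data: no random effects requested, none initialized
  expect_length(st$u, 0)
  # degenerate margin errors
  expect_error(starting_values(
    gene_pair_data(rep(0L, 40), y2, meta), blocks), "degenerate margin")
})

test_that("non-dropout random effects start at zero", {
  gp <- small_pair(seed = 13, m = 4, cells = 50)
  blocks <- build_design(gp, pair_spec())
  st <- starting_values(gp, blocks)
  expect_true(all(st$u[grep("^(mu|rho)", names(st$u))] == 0))
  expect_true(all(is.finite(st$u)) && all(is.finite(st$delta)))
})

test_that("inner fit ascends, converges, and a huge lambda shrinks u to zero", {
  gp <- small_pair(seed = 21, m = 4, cells = 50)
  blocks <- build_design(gp, pair_spec())
  st <- starting_values(gp, blocks)
  lam <- setNames(rep(1, length(blocks$comp_names)), blocks$comp_names)
  st$lambda <- lam
  f0 <- penalized_loglik(gp, blocks, st)
  fit <- fit_inner(gp, blocks, lam, st, fast_control())
  expect_gte(fit$loglik_pen, f0)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$grad)), 1e-5)
  expect_true(fit$edf >= blocks$n_fixed - 1e-6 &&
                fit$edf <= blocks$n_coef + 1e-6)
  big <- fit_inner(gp, blocks, lam * 0 + 1e6, fit$state, fast_control())
  expect_lt(max(abs(big$state$u)), 1e-3)
})

test_that("estimates are invariant to permuting the cells", {
  gp <- small_pair(seed = 31, m = 3, cells = 40)
  blocks <- build_design(gp, pair_spec())
  st <- starting_values(gp, blocks)
  lam <- setNames(rep(2, length(blocks$comp_names)), blocks$comp_names)
  f1 <- fit_inner(gp, blocks, lam, st, fast_control())
  set.seed(99)
  perm <- sample(length(gp$y1))
  meta_p <- gp$meta[perm, , drop = FALSE]
  meta_p$cell_id <- as.character(meta_p$cell_id)
  meta_p$patient <- as.character(meta_p$patient)
  meta_p$group <- as.character(meta_p$group)
  gp_p <- gene_pair_data(gp$y1[perm], gp$y2[perm], meta_p)
  blocks_p <- build_design(gp_p, pair_spec())
  st_p <- starting_values(gp_p, blocks_p)
  lam_p <- setNames(lam, blocks_p$comp_names)
  f2 <- fit_inner(gp_p, blocks_p, lam_p, st_p, fast_control())
  # reproducibility is bounded by double precision: with |loglik| ~ 1e3 the
  # optimizer cannot resolve objective differences below ~1e-13, which caps
  # iterate agreement near 1e-7
  expect_lt(max(abs(f1$state$delta - f2$state$delta)), 1e-7)
})

test_that("smoothing selection reacts to the size of the patient effects", {
  ctrl <- fast_control()
  big <- fit_pair(small_pair(seed = 41, m = 6, cells = 80,
                             re_sd = c(mu1 = 0.5, mu2 = 0.5, rho = 0.5,
                                       p1 = 0.1, p2 = 0.1)),
                  pair_spec(), ctrl)
  none <- fit_pair(small_pair(seed = 41, m = 6, cells = 80,
                              re_sd = c(mu1 = 1e-3, mu2 = 1e-3, rho = 1e-3,
                                        p1 = 1e-3, p2 = 1e-3)),
                   pair_spec(), ctrl)
  lam_big <- big$state$lambda["mu1:patient:group"]
  lam_none <- none$state$lambda["mu1:patient:group"]
  expect_lt(lam_big, lam_none)
  expect_true(is.finite(big$aic) && is.finite(none$aic))
})

test_that("iteration cap returns a flagged fit instead of an error", {
  gp <- small_pair(seed = 51, m = 3, cells = 30)
  blocks <- build_design(gp, pair_spec())
  st <- starting_values(gp, blocks)
  lam <- setNames(rep(1, length(blocks$comp_names)), blocks$comp_names)
  fit <- fit_inner(gp, blocks, lam, st, fit_control(max_iter = 2))
  expect_false(fit$converged)
  expect_true(is.finite(fit$loglik_pen))
})
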