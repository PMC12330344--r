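make_meta <- function(patients, groups = NULL, depth = 3e4) {
  n <- length(patients)
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   patient = patients,
                   depth = rep(depth, n), stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- groups
  df
}

test_that("random-intercept rows are standard basis vectors", {
  meta <- make_meta(rep(c("p1", "p2", "p3", "p4"), each = 2))
  gp <- gene_pair_data(rep(1L, 8), rep(2L, 8), meta)
  spec <- model_spec(rho = ~ (1 | patient))
  blocks <- build_design(gp, spec)
  Z <- blocks$theta$rho$Z
  expect_equal(ncol(Z), 4)
  expect_true(all(rowSums(Z) == 1))
  expect_equal(unname(Z[3, ]), c(0, 1, 0, 0)) # a cell of patient 2
})

test_that("a parameter without random effects gets a zero-column Z", {
  meta <- make_meta(rep("p1", 5))
  gp <- gene_pair_data(rep(1L, 5), rep(1L, 5), meta)
  blocks <- build_design(gp, model_spec(sigma1 = ~1))
  expect_equal(ncol(blocks$theta$sigma1$Z), 0)
})

test_that("patient-by-condition intercepts split into per-level variance components", {
  meta <- make_meta(rep(sprintf("p%d", 1:8), each = 4),
                    groups = rep(c("A", "A", "B", "B"), 8))
  gp <- gene_pair_data(rep(1L, 32), rep(1L, 32), meta)
  blocks <- build_design(gp, model_spec(rho = ~ group + (group | patient),
                                        condition = "group"))
  b <- blocks$theta$rho
  expect_equal(ncol(b$Z), 16)
  expect_equal(as.integer(table(b$comp)), c(8L, 8L))
  expect_equal(length(b$comp_names), 2)
  expect_true(all(rowSums(b$Z) == 1))
})

test_that("shared-component interaction grouping yields one component", {
  meta <- make_meta(rep(sprintf("p%d", 1:4), each = 4),
                    groups = rep(c("A", "B"), 8))
  gp <- gene_pair_data(rep(1L, 16), rep(1L, 16), meta)
  blocks <- build_design(gp, model_spec(mu1 = ~ group + (1 | patient:group)))
  b <- blocks$theta$mu1
  expect_equal(ncol(b$Z), 8)
  expect_equal(length(b$comp_names), 1)
})

test_that("penalty vector assigns one lambda per variance component", {
  meta <- make_meta(rep(sprintf("p%d", 1:4), each = 4),
                    groups = rep(c("A", "A", "B", "B"), 4))
  gp <- gene_pair_data(rep(1L, 16), rep(1L, 16), meta)
  blocks <- build_design(gp, model_spec(rho = ~ group + (group | patient)))
  lam <- setNames(c(3, 7), blocks$comp_names)
  pen <- coexmix:::.penalty_vector(blocks, lam)
  rand_pen <- pen[blocks$comp_id > 0]
  expect_equal(unname(rand_pen), rep(c(3, 7), each = 4))
  expect_true(all(pen[blocks$comp_id == 0] == 0))
})

test_that("inverse links at zero coefficients give the neutral parameters", {
  meta <- make_meta(rep("p1", 3), depth = 3e4)
  gp <- gene_pair_data(c(1L, 0L, 2L), c(0L, 1L, 2L), meta)
  blocks <- build_design(gp, model_spec())
  st <- list(delta = numeric(blocks$n_fixed), u = numeric(0))
  pp <- predict_params(blocks, st)
  expect_equal(pp$mu1, rep(3e4, 3))
  expect_equal(pp$sigma1, rep(1, 3))
  expect_equal(pp$rho, rep(0, 3))
  expect_equal(pp$p1, rep(0.5, 3))
})

test_that("link inversion is exact and the droplet contrast maps to tanh(-0.14)", {
  meta <- make_meta(rep("p1", 2), depth = 1)
  gp <- gene_pair_data(c(1L, 1L), c(1L, 1L), meta)
  blocks <- build_design(gp, model_spec(offset = FALSE))
  st <- list(delta = numeric(blocks$n_fixed), u = numeric(0))
  st$delta[grep("^rho:", blocks$coef_names[1:blocks$n_fixed])] <- atanh(0.3)
  expect_equal(predict_params(blocks, st)$rho[1], 0.3, tolerance = 1e-12)
  st$delta[grep("^rho:", blocks$coef_names[1:blocks$n_fixed])] <- 0.06 - 0.20
  expect_equal(predict_params(blocks, st)$rho[1], tanh(-0.14),
               tolerance = 1e-12)
  # round trips for all five link families over a grid
  eta <- seq(-5, 5, by = 0.5)
  expect_equal(log(exp(eta)), eta, tolerance = 1e-12)
  expect_equal(atanh(tanh(eta)), eta, tolerance = 1e-9)
  expect_equal(qlogis(plogis(eta)), eta, tolerance = 1e-9)
})

test_that("predicted parameters satisfy their range invariants for any coefficients", {
  meta <- make_meta(rep(c("p1", "p2"), 10), groups = rep(c("A", "B"), each = 10))
  gp <- gene_pair_data(rep(1L, 20), rep(1L, 20), meta)
  blocks <- build_design(gp, pair_spec())
  set.seed(3)
  for (i in 1:20) {
    st <- list(delta = rnorm(blocks$n_fixed, 0, 8),
               u = rnorm(blocks$n_coef - blocks$n_fixed, 0, 8))
    pp <- predict_params(blocks, st)
    expect_true(all(pp$mu1 > 0 & pp$mu2 > 0 & pp$sigma1 > 0 & pp$sigma2 > 0))
    expect_true(all(abs(pp$rho) < 1))
    expect_true(all(pp$p1 > 0 & pp$p1 < 1 & pp$p2 > 0 & pp$p2 < 1))
  }
})

test_that("design construction is deterministic and validates metadata", {
  meta <- make_meta(rep(c("p2", "p1"), each = 4),
                    groups = rep(c("B", "A"), 4))
  gp <- gene_pair_data(rep(1L, 8), rep(1L, 8), meta)
  b1 <- build_design(gp, pair_spec())
  b2 <- build_design(gp, pair_spec())
  expect_identical(b1$coef_names, b2$coef_names)
  expect_identical(b1$theta$rho$M, b2$theta$rho$M)
  # first-appearance order for random levels, sorted levels for conditions
  expect_match(b1$theta$p1$rand_names[1], "p2$")
  expect_equal(b1$condition_levels, c("A", "B"))
  bad <- make_meta(rep("p1", 3))
  bad$depth[2] <- NA
  expect_error(gene_pair_data(rep(1L, 3), rep(1L, 3), bad), "c002")
})
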