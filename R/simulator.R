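#' Scenario presets for the two-gene simulator
#'
#' Fixed-effect coefficients for the seven parameters under a two-level
#' condition, with the link-scale conventions of the model: `beta`/`alpha`/
#' `tau` are (intercept, condition increment) on the log / log / atanh
#' scales, while the dropout entries are natural-scale probabilities per
#' condition level (so a scenario without zero-inflation is `p = c(0, 0)`).
#' The droplet preset mimics a 10x-style dataset (shallow depth, low
#' over-dispersion, rare dropout; offset `log(3e4)`); the plate preset a
#' Smart-seq2-style dataset (deep, over-dispersed, more dropout; offset
#' `log(5e5)`).
#'
#' Random-intercept standard deviations are not part of the published
#' coefficient sets; the defaults (0.2 for the means and the correlation,
#' 0.1 for the dropout predictors) induce clearly visible within-patient
#' correlation and can be overridden.
#'
#' @param m number of patients.
#' @param cells_per_patient cells per patient.
#' @param ... preset fields to override (`beta1`, `beta2`, `alpha1`,
#'   `alpha2`, `tau`, `p1`, `p2`, `offset`, `re_sd`, `group_rule`).
#' @return list of class `coexmix_preset`.
#' @export
droplet_preset <- function(m = 10, cells_per_patient = 250, ...) {
  args <- utils::modifyList(list(
    name = "droplet",
    beta1 = c(-7.26, 0.45), beta2 = c(-7.10, 0.20),
    alpha1 = c(-0.46, -0.19), alpha2 = c(-0.44, -0.04),
    tau = c(0.06, -0.20),
    p1 = c(0.01, 0.05), p2 = c(0.01, 0.01),
    offset = log(3e4),
    group_rule = "split_half",
    m = m, cells_per_patient = cells_per_patient
  ), list(...))
  do.call(.make_preset, args)
}

#' @rdname droplet_preset
#' @export
plate_preset <- function(m = 10, cells_per_patient = 250, ...) {
  args <- utils::modifyList(list(
    name = "plate",
    beta1 = c(-7.43, -1.26), beta2 = c(-8.26, -0.65),
    alpha1 = c(0.51, 0.65), alpha2 = c(0.85, 0.26),
    tau = c(0.35, -0.34),
    p1 = c(0.08, 0.14), p2 = c(0.11, 0.21),
    offset = log(5e5),
    group_rule = "bernoulli",
    m = m, cells_per_patient = cells_per_patient
  ), list(...))
  do.call(.make_preset, args)
}

.make_preset <- function(name, beta1, beta2, alpha1, alpha2, tau, p1, p2,
                         offset, group_rule, m, cells_per_patient,
                         re_sd = c(mu1 = 0.2, mu2 = 0.2, rho = 0.2,
                                   p1 = 0.1, p2 = 0.1),
                         ...) {
  dots <- list(...)
  preset <- list(name = name, beta1 = beta1, beta2 = beta2, alpha1 = alpha1,
                 alpha2 = alpha2, tau = tau, p1 = p1, p2 = p2,
                 offset = offset, re_sd = re_sd, group_rule = group_rule,
                 m = m, cells_per_patient = cells_per_patient)
  for (nm in names(dots)) preset[[nm]] <- dots[[nm]]
  .validate_preset(preset)
  structure(preset, class = "coexmix_preset")
}

.validate_preset <- function(p) {
  for (f in c("beta1", "beta2", "alpha1", "alpha2", "tau", "p1", "p2"))
    if (length(p[[f]]) != 2 || any(!is.finite(p[[f]])))
      stop("preset field '", f, "' must be two finite values")
  if (any(p$p1 < 0 | p$p1 > 1) || any(p$p2 < 0 | p$p2 > 1))
    stop("dropout probabilities must be in [0, 1]")
  if (!p$group_rule %in% c("split_half", "bernoulli"))
    stop("unknown group rule: ", p$group_rule)
  if (p$m < 1 || p$cells_per_patient < 1) stop("m and cells_per_patient must be >= 1")
  sd_names <- c("mu1", "mu2", "rho", "p1", "p2")
  if (!all(sd_names %in% names(p$re_sd)) || any(p$re_sd[sd_names] < 0))
    stop("re_sd must provide non-negative sds for ", paste(sd_names, collapse = ", "))
  invisible(p)
}

# dropout probability on the natural scale for one gene: group-level values
# shifted by the patient random intercept on the logit scale; an exact zero
# stays an exact zero (no dropout channel at all)
.dropout_prob <- function(p_group, x, u_pat) {
  base <- p_group[1 + x]
  out <- numeric(length(base))
  pos <- base > 0
  out[pos] <- plogis(qlogis(base[pos]) + u_pat[pos])
  out
}

#' Simulate a multi-patient two-gene dataset
#'
#' Generates data by the model's own mechanism: draw patient-level random
#' intercepts, compute per-cell natural parameters through the links, draw a
#' standard bivariate Gaussian pair with the cell's correlation, transform
#' each coordinate through the NBII quantile function, and apply independent
#' Bernoulli dropout. Group assignment is half of each patient's cells per
#' condition for the droplet rule and an independent 50/50 per-cell split for
#' the plate rule. A single seed drives everything; per-patient substreams
#' are derived deterministically so datasets agree cell-for-cell on shared
#' patients when only `m` changes.
#'
#' @param preset a [droplet_preset] or [plate_preset] (possibly modified).
#' @param seed integer seed.
#' @return list of class `coexmix_sim` with `counts` (cells x 2), `meta`
#'   (cell_id, patient, group, depth), and `truth` (per-cell parameters and
#'   realized random effects).
#' @export
simulate_pair <- function(preset, seed = 1) {
  .validate_preset(preset)
  m <- preset$m; cpp <- preset$cells_per_patient
  set.seed(seed)
  sd <- preset$re_sd
  # random intercepts: patient-by-group for the means and the correlation,
  # patient-level for the dropout predictors
  u <- list(
    mu1 = matrix(rnorm(2 * m, 0, sd["mu1"]), m, 2),
    mu2 = matrix(rnorm(2 * m, 0, sd["mu2"]), m, 2),
    rho = matrix(rnorm(2 * m, 0, sd["rho"]), m, 2),
    p1 = rnorm(m, 0, sd["p1"]),
    p2 = rnorm(m, 0, sd["p2"])
  )
  res <- vector("list", m)
  for (i in seq_len(m)) {
    sub_seed <- (seed %% 100000L) * 20011L + i * 7919L
    set.seed(sub_seed)
    x <- if (preset$group_rule == "split_half") {
      rep(c(0L, 1L), c(ceiling(cpp / 2), floor(cpp / 2)))
    } else {
      rbinom(cpp, 1L, 0.5)
    }
    z1 <- rnorm(cpp); e <- rnorm(cpp)
    d1 <- runif(cpp); d2 <- runif(cpp)
    mu1 <- exp(preset$beta1[1] + preset$beta1[2] * x +
                 u$mu1[i, 1 + x] + preset$offset)
    mu2 <- exp(preset$beta2[1] + preset$beta2[2] * x +
                 u$mu2[i, 1 + x] + preset$offset)
    s1 <- exp(preset$alpha1[1] + preset$alpha1[2] * x)
    s2 <- exp(preset$alpha2[1] + preset$alpha2[2] * x)
    rho <- tanh(preset$tau[1] + preset$tau[2] * x + u$rho[i, 1 + x])
    p1 <- .dropout_prob(preset$p1, x, rep(u$p1[i], cpp))
    p2 <- .dropout_prob(preset$p2, x, rep(u$p2[i], cpp))
    z2 <- rho * z1 + sqrt(1 - rho^2) * e
    v1 <- nb_quantile(pmin(pnorm(z1), 1 - 1e-12), mu1, s1)
    v2 <- nb_quantile(pmin(pnorm(z2), 1 - 1e-12), mu2, s2)
    y1 <- ifelse(d1 < p1, 0L, as.integer(v1))
    y2 <- ifelse(d2 < p2, 0L, as.integer(v2))
    res[[i]] <- list(y1 = y1, y2 = y2, x = x,
                     params = data.frame(mu1 = mu1, mu2 = mu2, sigma1 = s1,
                                         sigma2 = s2, rho = rho,
                                         p1 = p1, p2 = p2))
  }
  y1 <- unlist(lapply(res, `[[`, "y1"))
  y2 <- unlist(lapply(res, `[[`, "y2"))
  x <- unlist(lapply(res, `[[`, "x"))
  params <- do.call(rbind, lapply(res, `[[`, "params"))
  n <- m * cpp
  patient <- rep(sprintf("P%02d", seq_len(m)), each = cpp)
  meta <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(n)),
    patient = patient,
    group = c("A", "B")[1 + x],
    depth = rep(exp(preset$offset), n),
    stringsAsFactors = FALSE
  )
  counts <- cbind(gene1 = y1, gene2 = y2)
  rownames(params) <- NULL
  structure(list(counts = counts, meta = meta,
                 truth = list(params = params, u = u, preset = preset,
                              seed = seed)),
            class = "coexmix_sim")
}

#' @exportS3Method base::print
print.coexmix_sim <- function(x, ...) {
  cat("simulated", x$truth$preset$name, "dataset:",
      nrow(x$counts), "cells,", x$truth$preset$m, "patients\n")
  invisible(x)
}

#' Convert a simulated dataset to gene-pair data
#'
#' @param sim a [simulate_pair] result.
#' @return a [gene_pair_data].
#' @export
as_gene_pair_data <- function(sim) {
  gene_pair_data(sim$counts[, 1], sim$counts[, 2], sim$meta,
                 genes = colnames(sim$counts))
}

#' Write a simulated dataset to disk
#'
#' Counts go out either as a dense TSV (genes x cells) or as an MTX triplet
#' directory (`matrix.mtx`, `features.tsv`, `barcodes.tsv`); metadata as a
#' TSV with columns cell_id/patient/group/depth; the generating truth as a
#' JSON manifest.
#'
#' @param sim a [simulate_pair] result.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- t(sim$counts) # genes x cells
  colnames(counts) <- sim$meta$cell_id
  if (format == "mtx") {
    write_counts(counts, dir, format = "mtx")
  } else {
    write_counts(counts, file.path(dir, "counts.tsv"), format = "tsv")
  }
  write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- unclass(sim$truth$preset)
  manifest$re_sd <- as.list(manifest$re_sd)
  manifest$seed <- sim$truth$seed
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
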