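test_that("presets carry the published coefficient sets and offsets", {
  d <- droplet_preset()
  expect_equal(c(d$beta1, d$beta2, d$alpha1, d$alpha2, d$tau),
               c(-7.26, 0.45, -7.10, 0.20, -0.46, -0.19, -0.44, -0.04,
                 0.06, -0.20))
  expect_equal(d$offset, log(3e4))
  p <- plate_preset()
  expect_equal(c(p$tau, p$p1, p$p2), c(0.35, -0.34, 0.08, 0.14, 0.11, 0.21))
  expect_equal(p$offset, log(5e5))
  expect_error(droplet_preset(p1 = c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(droplet_preset(tau = 1), "two finite values")
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  pr <- droplet_preset(m = 3, cells_per_patient = 40)
  s1 <- simulate_pair(pr, seed = 5)
  s2 <- simulate_pair(pr, seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$u, s2$truth$u)
  s3 <- simulate_pair(pr, seed = 6)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("without dropout or random effects the zero fraction matches the NB", {
  pr <- droplet_preset(m = 1, cells_per_patient = 1e5,
                       beta1 = c(-7.26, 0), beta2 = c(-7.10, 0),
                       alpha1 = c(-0.46, 0), alpha2 = c(-0.44, 0),
                       tau = c(0, 0), p1 = c(0, 0), p2 = c(0, 0),
                       re_sd = c(mu1 = 0, mu2 = 0, rho = 0, p1 = 0, p2 = 0))
  s <- simulate_pair(pr, seed = 17)
  mu <- exp(-7.26 + log(3e4)); sig <- exp(-0.46)
  p0 <- nb_cdf(0, mu, sig)
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_lt(abs(mean(s$counts[, 1] == 0) - p0), 3 * se)
  # dropout channel is genuinely off at p = 0
  expect_true(all(s$truth$params$p1 == 0))
})

test_that("strong positive copula correlation shows up in Spearman correlation", {
  pr <- droplet_preset(m = 1, cells_per_patient = 1e4,
                       tau = c(atanh(0.9), 0),
                       p1 = c(0, 0), p2 = c(0, 0),
                       re_sd = c(mu1 = 0, mu2 = 0, rho = 0, p1 = 0, p2 = 0))
  s <- simulate_pair(pr, seed = 23)
  expect_gt(cor(s$counts[, 1], s$counts[, 2], method = "spearman"), 0.7)
})

test_that("the condition contrast moves the within-group dependence in the -tau1 direction", {
  pr <- droplet_preset(m = 1, cells_per_patient = 2e4,
                       p1 = c(0, 0), p2 = c(0, 0),
                       re_sd = c(mu1 = 0, mu2 = 0, rho = 0, p1 = 0, p2 = 0))
  s <- simulate_pair(pr, seed = 29)
  gA <- s$meta$group == "A"
  corA <- cor(s$counts[gA, 1], s$counts[gA, 2], method = "spearman")
  corB <- cor(s$counts[!gA, 1], s$counts[!gA, 2], method = "spearman")
  expect_equal(sign(corA - corB), sign(-pr$tau[2])) # tau1 = -0.20
})

test_that("simulated metadata follows the group assignment rules", {
  sdrop <- simulate_pair(droplet_preset(m = 3, cells_per_patient = 10), seed = 2)
  per_pat <- table(sdrop$meta$patient, sdrop$meta$group)
  expect_true(all(per_pat == 5)) # half of each patient's cells per condition
  splate <- simulate_pair(plate_preset(m = 2, cells_per_patient = 500), seed = 2)
  frac <- mean(splate$meta$group == "B")
  expect_gt(frac, 0.4); expect_lt(frac, 0.6) # per-cell 50/50
  expect_equal(sdrop$meta$depth, rep(3e4, nrow(sdrop$meta)))
  expect_equal(splate$meta$depth, rep(5e5, nrow(splate$meta)))
})

test_that("round trip through disk preserves the dataset in both formats", {
  s <- simulate_pair(droplet_preset(m = 2, cells_per_patient = 15), seed = 4)
  for (fmt in c("tsv", "mtx")) {
    dir <- file.path(tempdir(), paste0("simout_", fmt))
    write_sim_dataset(s, dir, format = fmt)
    M <- read_counts(if (fmt == "mtx") dir else file.path(dir, "counts.tsv"))
    expect_equal(unname(M), unname(t(s$counts)))
    meta <- read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
    expect_equal(meta$patient, s$meta$patient)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    expect_equal(unlist(truth$tau), c(0.06, -0.20))
    unlink(dir, recursive = TRUE)
  }
})
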