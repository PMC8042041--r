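test_that("back-transformation is the exact inverse of standardization", {
  set.seed(40)
  for (i in 1:5) {
    m <- 200
    gamma <- rnorm(m, 0, 0.01); maf <- runif(m, 0.01, 0.5)
    n <- sample(1e4:1e6, 1)
    bt <- backTransform(gamma, 1 / sqrt(n), maf, n = n, role = "exposure")
    back <- standardizeExposure(bt$beta, bt$se, n)
    expect_lt(max(abs(back$gamma - gamma)), 1e-12)
    expect_lt(max(abs(back$se_gamma - 1 / sqrt(n))), 1e-12)

    Gamma <- rnorm(m, 0, 0.01); se_G <- runif(m, 1e-3, 1e-2)
    bt2 <- backTransform(Gamma, se_G, maf, role = "outcome")
    back2 <- standardizeOutcome(bt2$beta, bt2$se, maf)
    expect_lt(max(abs(back2$Gamma - Gamma)), 1e-12)
    expect_lt(max(abs(back2$se_Gamma - se_G)), 1e-12)
  }
  # zero preservation and the worked inverse example
  expect_equal(backTransform(0, 0.1, 0.3, 100, "exposure")$beta, 0)
  bt3 <- backTransform(0.0158114, 1 / sqrt(1e5), 0.25, n = 1e5,
                       role = "exposure", se_beta = 0.004)
  expect_equal(bt3$beta, 0.02, tolerance = 1e-5)
  expect_equal(bt3$se, 0.004)
  expect_error(backTransform(0.1, 0.01, 0.7, 100, "exposure"), "maf")
  expect_error(backTransform(0.1, 0.02, 0.3, 100, "exposure"),
               "must equal 1/sqrt")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- simConfig(m = 50, theta_true = 0.2, pleio_fraction = 0.2, seed = 99)
  s1 <- simulateMRData(cfg)
  s2 <- simulateMRData(cfg)
  expect_identical(records(s1$exposure[[1]]), records(s2$exposure[[1]]))
  expect_identical(records(s1$outcome[[1]]), records(s2$outcome[[1]]))
  expect_identical(s1$truth, s2$truth)
  # different seed changes the draws
  s3 <- simulateMRData(simConfig(m = 50, theta_true = 0.2,
                                 pleio_fraction = 0.2, seed = 100))
  expect_false(identical(records(s1$exposure[[1]])$beta,
                         records(s3$exposure[[1]])$beta))
})

test_that("the planted invalid fraction and truth bookkeeping are exact", {
  for (frac in c(0, 0.1, 0.4)) {
    sim <- simulateMRData(simConfig(m = 100, pleio_fraction = frac, seed = 5))
    expect_length(sim$truth$invalid_ids, round(frac * 100))
    expect_true(all(sim$truth$alpha[setdiff(names(sim$truth$alpha),
                                            sim$truth$invalid_ids)] == 0))
    if (frac > 0)
      expect_true(all(sim$truth$alpha[sim$truth$invalid_ids] != 0))
  }
})

test_that("noiseless generation is exactly identifiable end to end", {
  sim <- simulateMRData(simConfig(m = 40, theta_true = 0.35,
                                  pleio_fraction = 0, noise_scale = 0,
                                  seed = 41))
  h <- harmonizeSumstats(sim$exposure[[1]], sim$outcome[[1]])
  std <- standardizePairs(h)
  expect_equal(theta(mrIVW(std)), 0.35, tolerance = 1e-12)
  # standardization recovers the true standardized effects exactly
  expect_equal(records(std)$gamma[match(names(sim$truth$gamma),
                                        records(std)$snp)],
               unname(sim$truth$gamma), tolerance = 1e-12)
})

test_that("observed effects are uncorrelated under a null effect without overlap", {
  sim <- simulateMRData(simConfig(m = 10000, theta_true = 0,
                                  rho_overlap = 0, seed = 42))
  h <- harmonizeSumstats(sim$exposure[[1]], sim$outcome[[1]])
  std <- standardizePairs(h)
  ec <- effectCorrelation(std)
  expect_lt(abs(ec@rho), 3 / sqrt(10000))
})

test_that("sample overlap induces the configured error correlation", {
  # with theta 0 and gamma variance << noise, the observed correlation is
  # approximately rho_overlap
  sim <- simulateMRData(simConfig(m = 20000, theta_true = 0,
                                  rho_overlap = 0.5, sigma_gamma = 1e-5,
                                  seed = 43))
  h <- harmonizeSumstats(sim$exposure[[1]], sim$outcome[[1]])
  std <- standardizePairs(h)
  expect_equal(effectCorrelation(std)@rho, 0.5, tolerance = 0.03)
})

test_that("per-cohort tables meta-analyze to null-calibrated heterogeneity", {
  k <- 3
  sim <- simulateMRData(simConfig(m = 3000, theta_true = 0.2, k_cohorts = k,
                                  seed = 44))
  ma <- metaAnalyze(sim$exposure)
  Q <- ma@perVariant$Q
  expect_equal(ma@perVariant$k, rep(k, 3000))
  expect_lt(abs(mean(Q) - (k - 1)), 3 * sqrt(2 * (k - 1)) / sqrt(3000))
})

test_that("pleiotropy-test rejections among planted invalid variants rise with pleio_sd", {
  rates <- vapply(c(0.005, 0.02, 0.08), function(psd) {
    sim <- simulateMRData(simConfig(m = 400, theta_true = 0.3,
                                    pleio_fraction = 0.25, pleio_sd = psd,
                                    seed = 45))
    h <- harmonizeSumstats(sim$exposure[[1]], sim$outcome[[1]])
    std <- standardizePairs(h)
    pt <- mrPleiotropyTest(std, theta = 0.3)
    mean(pt$pvalue[records(std)$snp %in% sim$truth$invalid_ids] < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("LD blocks are emitted for clumping and allele noise exercises harmonization", {
  sim <- simulateMRData(simConfig(m = 30, ld_blocks = list(size = 3, r2 = 0.8),
                                  seed = 46))
  ids <- variantIds(sim$exposure[[1]])
  expect_equal(ldR2(sim$ld, ids[1], ids[2]), 0.8)   # same block
  expect_equal(ldR2(sim$ld, ids[1], ids[4]), 0)     # different blocks
  sel <- clumpVariants(sim$exposure[[1]], sim$ld, p1 = 1, r2_max = 0.1)
  expect_equal(length(sel), 10L)                    # one index per block

  sim2 <- simulateMRData(simConfig(m = 60, theta_true = 0.35, noise_scale = 0,
                                   inject_allele_noise = TRUE, seed = 47))
  h <- suppressMessages(harmonizeSumstats(sim2$exposure[[1]],
                                          sim2$outcome[[1]]))
  expect_gt(sum(records(h)$flipped), 0)             # swaps were injected
  std <- standardizePairs(h)
  expect_equal(theta(mrIVW(std)), 0.35, tolerance = 1e-10)
})

test_that("truth tables and manifests are written and readable", {
  sim <- simulateMRData(simConfig(m = 20, pleio_fraction = 0.1, seed = 48))
  dir <- tempfile()
  paths <- writeSimTruth(sim, dir)
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), 20)
  expect_equal(sum(tr$invalid), 2)
  man <- jsonlite::read_json(file.path(dir, "sim_manifest.json"))
  expect_equal(man$theta_true, 0.2)
  expect_equal(man$config$seed, 48)
})
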