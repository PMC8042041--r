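test_that("Wald ratio and its delta-method standard error behave as derived", {
  p <- standardizedPairs(0.02, 0.001, 0.04, 0.01)
  est <- mrWaldRatio(p)
  expect_equal(theta(est), 2.0)
  expect_equal(seTheta(est),
               sqrt(0.01^2 / 0.02^2 + 0.04^2 * 0.001^2 / 0.02^4))
  # null numerator
  expect_equal(theta(mrWaldRatio(standardizedPairs(0.02, 0.001, 0, 0.01))), 0)
  # se_gamma -> 0 limit collapses to se_Gamma/|gamma|
  est2 <- mrWaldRatio(standardizedPairs(0.02, 1e-12, 0.04, 0.01))
  expect_equal(seTheta(est2), 0.01 / 0.02, tolerance = 1e-6)
  expect_error(mrWaldRatio(standardizedPairs(0, 0.001, 0.04, 0.01)),
               "zero exposure effect")
})

test_that("IVW collapses to the Wald ratio for one instrument and is exact on noiseless data", {
  p1 <- standardizedPairs(0.02, 0.001, 0.04, 0.01)
  expect_equal(theta(mrIVW(p1)), theta(mrWaldRatio(p1)))

  set.seed(20)
  g <- rnorm(30, 0, 0.01)
  std <- standardizedPairs(g, 0.001, 0.5 * g, 0.01)
  expect_equal(theta(mrIVW(std)), 0.5, tolerance = 1e-14)
  expect_error(mrIVW(standardizedPairs(numeric(), numeric(), numeric(),
                                       numeric())), "no instrument")
  expect_error(mrIVW(standardizedPairs(c(0, 0), 0.001, c(0.1, 0.2), 0.01)),
               "no instrument")
})

test_that("IVW matches the explicit normal-equations oracle on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    m <- sample(2:50, 1)
    std <- standardizedPairs(rnorm(m, 0, 0.01), runif(m, 5e-4, 2e-3),
                             rnorm(m, 0, 0.01), runif(m, 5e-3, 2e-2),
                             maf = runif(m, 0.05, 0.5))
    est <- mrIVW(std)
    orc <- oracle_wls(std, intercept = FALSE)
    expect_equal(theta(est), orc$coef[1], tolerance = 1e-10)
    expect_equal(seTheta(est), orc$se[1], tolerance = 1e-10)
  }
})

test_that("Egger matches the weighted-least-squares oracle on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    m <- sample(3:50, 1)
    std <- standardizedPairs(rnorm(m, 0, 0.01), runif(m, 5e-4, 2e-3),
                             rnorm(m, 0, 0.01), runif(m, 5e-3, 2e-2))
    est <- mrEgger(std)
    orc <- oracle_wls(std, intercept = TRUE, orient = TRUE)
    expect_equal(est@intercept, orc$coef[1], tolerance = 1e-10)
    expect_equal(theta(est), orc$coef[2], tolerance = 1e-10)
    expect_equal(est@interceptSE, orc$se[1], tolerance = 1e-10)
    expect_equal(seTheta(est), orc$se[2], tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine data-generating model to machine precision", {
  set.seed(21)
  g <- abs(rnorm(20, 0, 0.01))  # pre-oriented
  std <- standardizedPairs(g, 0.001, 0.01 + 0.4 * g, 0.01)
  est <- mrEgger(std)
  expect_equal(theta(est), 0.4, tolerance = 1e-12)
  expect_equal(est@intercept, 0.01, tolerance = 1e-12)
  expect_error(mrEgger(standardizedPairs(1:2 / 100, 0.001, 1:2 / 100, 0.01)),
               "at least 3")
})

test_that("Egger separates directional pleiotropy from the causal slope under InSIDE", {
  # directional pleiotropy shifts every outcome effect by c; the intercept
  # absorbs it and the slope stays at the causal effect
  set.seed(22)
  m <- 500; th <- 0.3; c0 <- 0.012
  g <- abs(rnorm(m, 0.01, 0.005))
  se_G <- 0.01
  G <- c0 + th * g + rnorm(m, 0, se_G)
  est <- mrEgger(standardizedPairs(g, 1e-3, G, se_G))
  expect_lt(abs(theta(est) - th), 3 * seTheta(est))
  expect_lt(abs(est@intercept - c0), 3 * est@interceptSE)
  # balanced pleiotropy: intercept within 3 se of zero
  G2 <- th * g + rnorm(m, 0, se_G) + rnorm(m, 0, 0.005)
  est2 <- mrEgger(standardizedPairs(g, 1e-3, G2, se_G))
  expect_lt(abs(est2@intercept), 3 * est2@interceptSE)
})

test_that("estimators are sign-equivariant in the instrument orientation", {
  set.seed(23)
  std <- rand_pairs(40, theta = 0.25, seed = 23)
  p <- records(std)
  flip_both <- standardizedPairs(-p$gamma, p$se_gamma, -p$Gamma, p$se_Gamma)
  flip_out <- standardizedPairs(p$gamma, p$se_gamma, -p$Gamma, p$se_Gamma)
  for (f in list(mrIVW, function(x) mrEgger(x), function(x) mrIMRP(x))) {
    expect_equal(theta(f(flip_both)), theta(f(std)), tolerance = 1e-12)
    expect_equal(theta(f(flip_out)), -theta(f(std)), tolerance = 1e-12)
  }
})

test_that("odds-ratio conversion matches its closed form", {
  expect_equal(unname(toOddsRatio(0, 0.1)[1]), 1)
  or0 <- toOddsRatio(0, 0.1)
  expect_equal(or0[["or"]] / or0[["ci_low"]], or0[["ci_high"]] / or0[["or"]])
  expect_equal(unname(toOddsRatio(log(2), 0)), c(2, 2, 2))
  or <- toOddsRatio(0.5, 0.1)
  expect_equal(or[["or"]], 1.6487, tolerance = 1e-4)
  expect_equal(or[["ci_low"]], 1.3554, tolerance = 1e-4)
  expect_equal(or[["ci_high"]], 2.0056, tolerance = 1e-4)
  # estimator results carry consistent OR fields
  est <- mrIVW(rand_pairs(20, seed = 1))
  expect_equal(unname(oddsRatio(est)[1]), exp(theta(est)))
  expect_lte(est@ciLow, est@oddsRatio)
  expect_gte(est@ciHigh, est@oddsRatio)
})

test_that("pleiotropy test reduces correctly in its degenerate configurations", {
  # zero residual -> t = 0, p = 1
  p <- standardizedPairs(0.02, 0.001, 0.4 * 0.02, 0.01)
  r <- mrPleiotropyTest(p, theta = 0.4)
  expect_equal(r$t_stat, 0)
  expect_equal(r$pvalue, 1)
  # theta = 0, rho = 0 -> outcome z-score
  p2 <- standardizedPairs(0.02, 0.001, 0.03, 0.01)
  r2 <- mrPleiotropyTest(p2, theta = 0)
  expect_equal(r2$t_stat, 0.03 / 0.01)
  # overlap correction enters the variance with the cross term
  r3 <- mrPleiotropyTest(p2, theta = 0.5, rho_overlap = 0.3)
  v <- 0.01^2 + 0.25 * 0.001^2 - 2 * 0.5 * 0.3 * 0.01 * 0.001
  expect_equal(r3$t_stat, (0.03 - 0.5 * 0.02) / sqrt(v))
  # Bonferroni flag implies nominal flag
  set.seed(24)
  std <- rand_pairs(200, n_pleio = 20, pleio_sd = 0.05, seed = 24)
  rt <- mrPleiotropyTest(std, theta = 0.3)
  expect_true(all(rt$flagged_nominal[rt$flagged_bonferroni]))
})

test_that("pleiotropy test holds its nominal type-I error under the null", {
  set.seed(25)
  m <- 10000; th <- 0.3
  std <- rand_pairs(m, theta = th, seed = 25)
  r <- mrPleiotropyTest(std, theta = th)
  rate <- mean(r$pvalue < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("iterative pruning is a fixed point on clean data and reproduces IVW at alpha 0", {
  # tight noise: residuals are exactly on the causal line, nothing excluded
  clean <- rand_pairs(50, theta = 0.3, noise = FALSE, seed = 26)
  est <- mrIMRP(clean)
  expect_lte(est@iterations, 2L)
  expect_true(est@converged)
  expect_length(est@excluded, 0)
  expect_equal(theta(est), theta(mrIVW(clean)), tolerance = 1e-12)

  std <- rand_pairs(50, theta = 0.3, seed = 26)
  est0 <- mrIMRP(std, alpha_pleio = 0)
  expect_equal(theta(est0), theta(mrIVW(std)), tolerance = 1e-14)
  expect_equal(seTheta(est0), seTheta(mrIVW(std)), tolerance = 1e-14)
  expect_length(est0@excluded, 0)
})

test_that("iterative pruning excludes planted pleiotropic instruments and recovers theta", {
  # plant |alpha| at exactly 10x the outcome noise sd of 0.01
  set.seed(27)
  m <- 100; se_g <- 1 / sqrt(650000); se_G <- 0.01
  gamma <- rnorm(m, 0, 0.01)
  alpha <- numeric(m)
  truth_invalid <- sort(sample.int(m, 10))
  alpha[truth_invalid] <- sample(c(-1, 1), 10, TRUE) * 10 * se_G
  std <- standardizedPairs(gamma + rnorm(m, 0, se_g), se_g,
                           0.3 * gamma + alpha + rnorm(m, 0, se_G), se_G)
  est <- mrIMRP(std)
  planted <- records(std)$snp[truth_invalid]
  expect_true(all(planted %in% est@excluded))
  false_pos <- setdiff(est@excluded, planted)
  expect_lte(length(false_pos), 90 * 0.05 + 3 * sqrt(90 * 0.05 * 0.95))
  expect_lt(abs(theta(est) - 0.3), 3 * seTheta(est))
  expect_equal(est@nSNPs + length(est@excluded), 100L)
  # diagnostics table covers every input instrument
  expect_equal(nrow(est@pleiotropy), 100L)
})

test_that("all-instrument exclusion and insufficient instruments raise errors", {
  std <- standardizedPairs(c(0.02, 0.021, 0.019), 1e-4,
                           c(0.5, -0.5, 0.45), 1e-4)
  expect_error(mrIMRP(std), "all instruments excluded")
  expect_error(mrIMRP(rand_pairs(2, seed = 1)), "at least 3")
})
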