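two_study <- function(b1, b2, se1, se2) {
  list(make_table(snp = "rs1", beta = b1, se = se1, n = 1000),
       make_table(snp = "rs1", beta = b2, se = se2, n = 2000))
}

test_that("fixed-effect combination matches the hand-computed two-study example", {
  ma <- metaAnalyze(two_study(0.1, 0.3, 0.1, 0.1))
  rec <- records(ma@table)
  expect_equal(rec$beta, 0.2)
  expect_equal(rec$se, 0.1 / sqrt(2))
  expect_equal(ma@perVariant$Q, 2.0)
  expect_equal(ma@perVariant$k, 2L)
  expect_equal(ma@perVariant$Q_pvalue, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(rec$n, 3000)
  expect_equal(rec$p, 2 * pnorm(-abs(0.2 / (0.1 / sqrt(2)))))
})

test_that("single-study input passes through with undefined heterogeneity", {
  tab <- make_table(beta = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.03))
  ma <- metaAnalyze(list(tab))
  expect_equal(records(ma@table)$beta, records(tab)$beta)
  expect_equal(records(ma@table)$se, records(tab)$se)
  expect_true(all(is.na(ma@perVariant$Q)))
  expect_false(any(ma@perVariant$het_flag))
})

test_that("identical studies give zero heterogeneity and precision gains of sqrt(k)", {
  for (k in 2:4) {
    ma <- metaAnalyze(rep(list(make_table(snp = "rs1", beta = 0.2, se = 0.1)), k))
    rec <- records(ma@table)
    expect_equal(rec$beta, 0.2)
    expect_equal(rec$se, 0.1 / sqrt(k))       # k^{-1/2} scaling
    expect_equal(ma@perVariant$Q, 0)
    expect_equal(ma@perVariant$Q_pvalue, 1)
    expect_false(ma@perVariant$het_flag)
  }
})

test_that("equal weights reduce the combination to the arithmetic mean", {
  set.seed(3)
  betas <- rnorm(5, 0, 0.1)
  tabs <- lapply(betas, function(b) make_table(snp = "rs1", beta = b, se = 0.05))
  ma <- metaAnalyze(tabs)
  expect_equal(records(ma@table)$beta, mean(betas))
})

test_that("meta precision is never worse than the best single study", {
  set.seed(4)
  for (rep in 1:20) {
    ses <- runif(3, 0.01, 0.2)
    tabs <- Map(function(b, s) make_table(snp = "rs1", beta = b, se = s),
                rnorm(3), ses)
    ma <- metaAnalyze(tabs)
    expect_lte(records(ma@table)$se, min(ses))
  }
})

test_that("combination agrees with the metafor fixed-effect oracle", {
  set.seed(5)
  for (rep in 1:10) {
    b <- rnorm(4, 0, 0.2); s <- runif(4, 0.02, 0.3)
    ma <- metaAnalyze(Map(function(bi, si) make_table(snp = "rs1", beta = bi, se = si), b, s))
    or <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(records(ma@table)$beta, as.numeric(or$beta), tolerance = 1e-10)
    expect_equal(records(ma@table)$se, or$se, tolerance = 1e-10)
    expect_equal(ma@perVariant$Q, or$QE, tolerance = 1e-10)
  }
})

test_that("swapped and strand-flipped cohort alleles are realigned; conflicts dropped", {
  t1 <- make_table(snp = "rs1", ea = "A", oa = "G", beta = 0.2, se = 0.1, eaf = 0.3)
  swapped <- make_table(snp = "rs1", ea = "G", oa = "A", beta = -0.2, se = 0.1, eaf = 0.7)
  ma <- metaAnalyze(list(t1, swapped))
  expect_equal(records(ma@table)$beta, 0.2)   # sign realigned: no heterogeneity
  expect_equal(ma@perVariant$Q, 0)
  expect_equal(records(ma@table)$eaf, 0.3)

  complemented <- make_table(snp = "rs1", ea = "T", oa = "C", beta = 0.2, se = 0.1, eaf = 0.3)
  ma2 <- metaAnalyze(list(t1, complemented))
  expect_equal(records(ma2@table)$beta, 0.2)
  expect_equal(ma2@perVariant$k, 2L)

  conflicting <- make_table(snp = "rs1", ea = "C", oa = "G", beta = 0.5, se = 0.1)
  expect_message(ma3 <- metaAnalyze(list(t1, conflicting)), "unreconcilable")
  expect_equal(records(ma3@table)$beta, 0.2)  # conflicting cohort excluded
  expect_equal(ma3@perVariant$k, 1L)
})

test_that("variants missing from some cohorts are combined over the contributing ones", {
  t1 <- make_table(snp = c("rs1", "rs2"), beta = 0.1, se = 0.1)
  t2 <- make_table(snp = c("rs2", "rs3"), beta = 0.3, se = 0.1)
  ma <- metaAnalyze(list(t1, t2))
  pv <- ma@perVariant
  expect_equal(pv$k[match(c("rs1", "rs2", "rs3"), pv$snp)], c(1L, 2L, 1L))
  rec <- records(ma@table)
  expect_equal(rec$beta[rec$snp == "rs2"], 0.2)
  expect_equal(rec$beta[rec$snp == "rs3"], 0.3)
})

test_that("null heterogeneity statistics follow the chi-square reference", {
  set.seed(6)
  m <- 5000; k <- 3
  beta_true <- rnorm(m, 0, 0.02)
  tabs <- lapply(1:k, function(j)
    make_table(snp = sprintf("v%05d", 1:m),
               beta = beta_true + rnorm(m, 0, 0.05), se = 0.05))
  ma <- metaAnalyze(tabs)
  Q <- ma@perVariant$Q
  # mean of chi2_{k-1} is k-1 = 2, sd sqrt(2(k-1)) = 2
  expect_lt(abs(mean(Q) - (k - 1)), 3 * sqrt(2 * (k - 1)) / sqrt(m))
  # Bonferroni flagging is rare under the null
  expect_lte(sum(ma@perVariant$het_flag), 3)
})

test_that("the Bonferroni heterogeneity screen flags a planted discordant variant", {
  m <- 50
  b <- rep(0.1, m)
  t1 <- make_table(snp = sprintf("v%02d", 1:m), beta = b, se = 0.01)
  b2 <- b; b2[7] <- 0.25   # 15 se discrepancy splits across two cohorts
  t2 <- make_table(snp = sprintf("v%02d", 1:m), beta = b2, se = 0.01)
  ma <- metaAnalyze(list(t1, t2))
  expect_true(ma@perVariant$het_flag[7])
  expect_equal(sum(ma@perVariant$het_flag), 1L)
  # flagged variants are retained, not removed
  expect_equal(nVariants(ma@table), m)
})
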