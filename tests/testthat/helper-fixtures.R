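# Fixture builders and independent oracles shared across the suite.

# quick canonical summary-statistic table from defaults
make_table <- function(snp = c("rs1", "rs2", "rs3"),
                       chr = "1",
                       pos = seq(1e5, by = 1e5, length.out = length(snp)),
                       ea = "A", oa = "G", eaf = 0.3,
                       beta = 0.1, se = 0.02, p = NULL, n = 10000,
                       trait_type = "quantitative") {
  m <- length(snp)
  rec <- data.frame(snp = snp, chr = rep_len(chr, m),
                    pos = as.integer(rep_len(pos, m)),
                    ea = rep_len(ea, m), oa = rep_len(oa, m),
                    eaf = rep_len(eaf, m), beta = rep_len(beta, m),
                    se = rep_len(se, m), stringsAsFactors = FALSE)
  rec$p <- if (is.null(p)) pmax(2 * pnorm(-abs(rec$beta / rec$se)), 1e-300)
           else rep_len(p, m)
  rec$n <- rep_len(n, m)
  pleioMR:::.sumstats(rec, trait_type = trait_type)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random standardized instrument set with optional planted pleiotropy
rand_pairs <- function(m, theta = 0.3, sigma_gamma = 0.01,
                       se_gamma = 1 / sqrt(650000), se_Gamma = 1 / sqrt(10000),
                       n_pleio = 0, pleio_sd = 0, pleio_mean = 0,
                       noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gamma <- rnorm(m, 0, sigma_gamma)
  alpha <- numeric(m)
  invalid <- integer()
  if (n_pleio > 0) {
    invalid <- sort(sample.int(m, n_pleio))
    alpha[invalid] <- rnorm(n_pleio, pleio_mean, pleio_sd)
  }
  Gamma <- theta * gamma + alpha
  g_hat <- gamma; G_hat <- Gamma
  if (noise) {
    g_hat <- g_hat + rnorm(m, 0, se_gamma)
    G_hat <- G_hat + rnorm(m, 0, se_Gamma)
  }
  std <- standardizedPairs(g_hat, se_gamma, G_hat, se_Gamma)
  attr(std, "invalid") <- invalid
  attr(std, "theta") <- theta
  std
}

# independent weighted-least-squares oracle via lm()
oracle_wls <- function(pairs, intercept = FALSE, orient = FALSE) {
  p <- records(pairs)
  g <- p$gamma; G <- p$Gamma
  if (orient) {
    s <- ifelse(g < 0, -1, 1)
    g <- s * g; G <- s * G
  }
  w <- 1 / p$se_Gamma^2
  fit <- if (intercept) lm(G ~ g, weights = w) else lm(G ~ g - 1, weights = w)
  cf <- summary(fit)$coefficients
  # lm rescales its dispersion; with known variances the weighted
  # normal-equation SEs are (X'WX)^{-1} directly
  X <- if (intercept) cbind(1, g) else cbind(g)
  V <- solve(t(X) %*% (w * X))
  list(coef = unname(coef(fit)), se = unname(sqrt(diag(V))))
}

# naive clumping oracle: literal transcription of the greedy procedure,
# working on a full named r2 matrix with no shared code with the package
oracle_clump <- function(df, r2mat, p1, r2_max, window_kb) {
  cand <- df[df$p < p1, , drop = FALSE]
  cand <- cand[order(cand$p, cand$snp), , drop = FALSE]
  chosen <- character()
  while (nrow(cand) > 0L) {
    idx <- cand[1L, ]
    chosen <- c(chosen, idx$snp)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    kill <- logical(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      if (cand$chr[j] != idx$chr) next
      if (abs(cand$pos[j] - idx$pos) > window_kb * 1000) next
      r2 <- if (idx$snp %in% rownames(r2mat) && cand$snp[j] %in% rownames(r2mat))
        r2mat[idx$snp, cand$snp[j]] else 0
      if (r2 >= r2_max) kill[j] <- TRUE
    }
    cand <- cand[!kill, , drop = FALSE]
  }
  chosen
}

# random clumping instance on one or two chromosomes, m <= 20
rand_clump_instance <- function(m, seed) {
  set.seed(seed)
  snp <- sprintf("s%02d", sample(m))
  chr <- sample(c("1", "2"), m, replace = TRUE, prob = c(0.8, 0.2))
  pos <- sample.int(2e6, m)
  p <- 10^runif(m, -25, -4)
  A <- matrix(runif(m * m), m, m)
  r2 <- (A + t(A)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(snp, snp)
  list(df = data.frame(snp = snp, chr = chr, pos = pos, p = p,
                       stringsAsFactors = FALSE),
       ld = ldInfo(snp, r2), r2mat = r2)
}
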