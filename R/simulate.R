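#' Simulation configuration
#'
#' Collects the generative parameters for [simulateMRData()] and validates
#' their ranges. Defaults emulate the statistical structure of a
#' well-powered exposure GWAS paired with a modest binary-outcome GWAS:
#' standardized instrument effects with standard deviation `sigma_gamma =
#' 0.01` (the scale of genome-wide-significant effects in biobank-sized
#' GWAS), a configurable fraction of horizontally pleiotropic instruments
#' (balanced or directional), uniform minor allele frequencies, and
#' optional exposure-outcome sample-overlap correlation.
#'
#' @param m number of instruments.
#' @param theta_true causal effect on the standardized scale.
#' @param maf_range minor-allele-frequency range within (0, 0.5].
#' @param n_exposure,n_outcome per-cohort sample sizes.
#' @param k_cohorts number of cohorts generated for each of the exposure
#'   and outcome (>= 1).
#' @param pleio_fraction fraction of invalid (pleiotropic) instruments.
#' @param pleio_mode `"balanced"` (mean-zero direct effects) or
#'   `"directional"` (mean `pleio_mean`).
#' @param pleio_sd,pleio_mean pleiotropy distribution parameters on the
#'   standardized scale.
#' @param rho_overlap correlation between exposure and outcome sampling
#'   errors in (-1, 1) (shared participants).
#' @param sigma_gamma standard deviation of true instrument effects.
#' @param noise_scale multiplier on the sampling noise (0 gives noiseless
#'   estimates equal to the true effects; 1 is the calibrated
#'   `1/sqrt(n)` noise).
#' @param ld_blocks optional list `list(size =, r2 =)`: consecutive blocks
#'   of `size` variants share positions within one clumping window and
#'   pairwise squared correlation `r2`; variants in different blocks are
#'   independent and distant.
#' @param inject_allele_noise if `TRUE`, a fraction of outcome records get
#'   swapped alleles (sign-flipped beta, mirrored eaf) and palindromic
#'   allele pairs are allowed, to exercise harmonization.
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(m = 100L, theta_true = 0.2, maf_range = c(0.05, 0.5),
                      n_exposure = 650000, n_outcome = 10000,
                      k_cohorts = 1L, pleio_fraction = 0,
                      pleio_mode = c("balanced", "directional"),
                      pleio_sd = 0.02, pleio_mean = 0.02, rho_overlap = 0,
                      sigma_gamma = 0.01, noise_scale = 1,
                      ld_blocks = NULL, inject_allele_noise = FALSE,
                      seed = 1L) {
  pleio_mode <- match.arg(pleio_mode)
  stopifnot(m >= 1, pleio_fraction >= 0, pleio_fraction <= 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exposure >= 2, n_outcome >= 2, k_cohorts >= 1L,
            abs(rho_overlap) < 1, sigma_gamma > 0, noise_scale >= 0,
            pleio_sd >= 0)
  if (!is.null(ld_blocks))
    stopifnot(is.list(ld_blocks), ld_blocks$size >= 1,
              ld_blocks$r2 >= 0, ld_blocks$r2 <= 1)
  structure(list(m = as.integer(m), theta_true = theta_true,
                 maf_range = maf_range, n_exposure = n_exposure,
                 n_outcome = n_outcome, k_cohorts = as.integer(k_cohorts),
                 pleio_fraction = pleio_fraction, pleio_mode = pleio_mode,
                 pleio_sd = pleio_sd, pleio_mean = pleio_mean,
                 rho_overlap = rho_overlap, sigma_gamma = sigma_gamma,
                 noise_scale = noise_scale, ld_blocks = ld_blocks,
                 inject_allele_noise = inject_allele_noise,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Back-transform standardized effects to the per-allele scale
#'
#' Exact algebraic inverse of the standardization equations, so that
#' re-standardizing recovers the input to machine precision.
#'
#' For the outcome role the inverse is fully determined:
#' `beta = x / sqrt(2*maf*(1-maf))`, `se = se_std / sqrt(2*maf*(1-maf))`.
#' For the exposure role the per-allele standard error is a free scale (the
#' standardization divides it out); unless `se_beta` is supplied, the
#' standard GWAS approximation `se_beta = 1/sqrt(2*maf*(1-maf)*n)` is used,
#' giving `beta = x * se_beta * sqrt(n)`.
#'
#' @param x standardized effect(s) (`gamma` or `Gamma`).
#' @param se_std standardized standard error(s); for the exposure role this
#'   must equal `1/sqrt(n)`.
#' @param maf minor allele frequency in (0, 0.5].
#' @param n sample size (exposure role), >= 2.
#' @param role `"exposure"` or `"outcome"`.
#' @param se_beta optional explicit per-allele standard error for the
#'   exposure role.
#' @return data.frame with columns `beta`, `se`.
#' @examples
#' backTransform(0.0158114, 1 / sqrt(1e5), maf = 0.25, n = 1e5,
#'               role = "exposure", se_beta = 0.004)
#' @export
backTransform <- function(x, se_std, maf, n = NULL,
                          role = c("exposure", "outcome"), se_beta = NULL) {
  role <- match.arg(role)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (role == "outcome") {
    w <- sqrt(2 * maf * (1 - maf))
    return(data.frame(beta = x / w, se = se_std / w))
  }
  if (is.null(n) || any(n < 2)) stop("exposure role needs n >= 2")
  if (any(abs(se_std - 1 / sqrt(n)) > 1e-8 * se_std))
    stop("exposure se_std must equal 1/sqrt(n)")
  if (is.null(se_beta)) se_beta <- 1 / sqrt(2 * maf * (1 - maf) * n)
  data.frame(beta = x * se_beta * sqrt(n), se = se_beta)
}

#' Simulate multi-cohort GWAS summary statistics with known causal
#' structure
#'
#' Generates per-cohort exposure and outcome summary-statistic tables whose
#' true standardized effects follow the two-sample MR decomposition: true
#' instrument effects `gamma_i ~ N(0, sigma_gamma^2)`, direct (pleiotropic)
#' effects `alpha_i` zero for valid instruments and normal
#' (`N(pleio_mean, pleio_sd^2)` directional, `N(0, pleio_sd^2)` balanced)
#' for the planted invalid fraction, and outcome effects
#' `Gamma_i = theta_true*gamma_i + alpha_i`. Per-cohort observed
#' standardized estimates add `noise_scale/sqrt(n)` sampling noise,
#' correlated `rho_overlap` between the exposure and outcome draws of the
#' same cohort. Observed effects are back-transformed to the per-allele
#' scale via [backTransform()] so that the standardization step of the
#' analysis pipeline is exercised end to end. Variants are placed far apart
#' on chromosome 1 (independent) unless `ld_blocks` groups them into
#' within-window blocks with constant pairwise r-squared, emitted in the
#' accompanying [LDInfo].
#'
#' @param config a [simConfig()] list.
#' @return list with elements `exposure` (list of [SumStats], one per
#'   cohort), `outcome` (likewise), `ld` ([LDInfo]), and `truth` (list:
#'   `theta_true`, `invalid_ids`, `alpha`, `gamma`, `config`).
#' @export
simulateMRData <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cf <- config
  set.seed(cf$seed)
  m <- cf$m
  snp <- sprintf("rs%05d", seq_len(m))
  maf <- stats::runif(m, cf$maf_range[1], cf$maf_range[2])

  # genomic layout: independent loci sit 5 Mb apart (far outside any
  # clumping window), at most 40 loci per chromosome to keep coordinates in
  # integer range; LD-block members share a window 10 kb apart
  if (is.null(cf$ld_blocks)) {
    block <- seq_len(m)
    within <- integer(m)
  } else {
    bs <- as.integer(cf$ld_blocks$size)
    block <- (seq_len(m) - 1L) %/% bs + 1L
    within <- (seq_len(m) - 1L) %% bs
  }
  chr <- as.character(1L + (block - 1L) %/% 40L)
  pos <- 1L + ((block - 1L) %% 40L) * 5000000L + within * 10000L
  # LD is only informative within blocks; independent variants sit outside
  # any clumping window, so an empty lookup suffices (and stays O(1) in m)
  ld <- if (is.null(cf$ld_blocks)) {
    ldInfo(character(), matrix(numeric(), 0, 0))
  } else {
    r2 <- diag(1, m)
    if (cf$ld_blocks$r2 > 0)
      for (b in unique(block)) {
        i <- which(block == b)
        r2[i, i] <- cf$ld_blocks$r2
        r2[cbind(i, i)] <- 1
      }
    ldInfo(snp, r2)
  }

  n_invalid <- round(cf$pleio_fraction * m)
  invalid <- if (n_invalid > 0) sort(sample.int(m, n_invalid)) else integer()
  gamma_true <- stats::rnorm(m, 0, cf$sigma_gamma)
  alpha <- numeric(m)
  if (n_invalid > 0)
    alpha[invalid] <- stats::rnorm(
      n_invalid,
      mean = if (cf$pleio_mode == "directional") cf$pleio_mean else 0,
      sd = cf$pleio_sd)
  Gamma_true <- cf$theta_true * gamma_true + alpha

  # allele pairs; non-palindromic by default
  np_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                    c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(np_pairs), m, replace = TRUE)
  ea <- np_pairs[pick, 1L]; oa <- np_pairs[pick, 2L]
  if (cf$inject_allele_noise) {
    pal <- sample.int(m, max(1L, m %/% 10L))
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pp <- sample.int(4L, length(pal), replace = TRUE)
    ea[pal] <- pal_pairs[pp, 1L]; oa[pal] <- pal_pairs[pp, 2L]
  }

  make_cohort <- function(n, role, std_hat, se_std) {
    bt <- backTransform(std_hat, se_std, maf, n = n, role = role)
    z <- bt$beta / bt$se
    p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    rec <- data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
                      eaf = maf, beta = bt$beta, se = bt$se, p = p, n = n,
                      stringsAsFactors = FALSE)
    rec
  }

  exposure <- vector("list", cf$k_cohorts)
  outcome <- vector("list", cf$k_cohorts)
  for (k in seq_len(cf$k_cohorts)) {
    se_g <- 1 / sqrt(cf$n_exposure)
    se_G <- 1 / sqrt(cf$n_outcome)
    # correlated sampling errors (sample overlap)
    e1 <- stats::rnorm(m)
    e2 <- cf$rho_overlap * e1 +
      sqrt(1 - cf$rho_overlap^2) * stats::rnorm(m)
    gamma_hat <- gamma_true + cf$noise_scale * se_g * e1
    Gamma_hat <- Gamma_true + cf$noise_scale * se_G * e2
    rec_e <- make_cohort(cf$n_exposure, "exposure", gamma_hat, se_g)
    rec_o <- make_cohort(cf$n_outcome, "outcome", Gamma_hat, se_G)
    if (cf$inject_allele_noise) {
      swap <- sample.int(m, max(1L, m %/% 5L))
      rec_o$beta[swap] <- -rec_o$beta[swap]
      rec_o$eaf[swap] <- 1 - rec_o$eaf[swap]
      tmp <- rec_o$ea[swap]
      rec_o$ea[swap] <- rec_o$oa[swap]
      rec_o$oa[swap] <- tmp
    }
    exposure[[k]] <- .sumstats(rec_e, trait_name = "exposure",
                               trait_type = "quantitative",
                               ancestry = sprintf("cohort_%d", k))
    outcome[[k]] <- .sumstats(rec_o, trait_name = "outcome",
                              trait_type = "binary",
                              ancestry = sprintf("cohort_%d", k))
  }
  truth <- list(theta_true = cf$theta_true, invalid_ids = snp[invalid],
                alpha = stats::setNames(alpha, snp),
                gamma = stats::setNames(gamma_true, snp), config = cf)
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Write a simulation truth table and manifest
#'
#' Emits the generating truth as TSV (snp, true gamma, alpha, invalid flag)
#' plus a machine-readable JSON manifest echoing the configuration and
#' seed.
#'
#' @param sim result of [simulateMRData()].
#' @param dir output directory (created if needed).
#' @return character vector of the two paths written, invisibly.
#' @export
writeSimTruth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$truth
  df <- data.frame(snp = names(tr$gamma), gamma_true = unname(tr$gamma),
                   alpha = unname(tr$alpha),
                   invalid = names(tr$gamma) %in% tr$invalid_ids)
  tpath <- file.path(dir, "truth.tsv")
  utils::write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- file.path(dir, "sim_manifest.json")
  cfg <- tr$config
  cfg$ld_blocks <- if (is.null(cfg$ld_blocks)) NULL else as.list(cfg$ld_blocks)
  jsonlite::write_json(list(theta_true = tr$theta_true,
                            config = unclass(cfg)),
                       mpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tpath, mpath))
}
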