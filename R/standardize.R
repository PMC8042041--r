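#' Standardize an exposure effect
#'
#' Rescales a per-allele exposure effect to the unitless instrument scale:
#' `gamma = beta / (se * sqrt(n))` with `se_gamma = 1 / sqrt(n)`. The
#' per-variant z-score is preserved exactly (`gamma/se_gamma = beta/se`),
#' and the transform is invariant to a common rescaling of `(beta, se)`.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @param n exposure GWAS sample size(s), at least 2.
#' @return data.frame with columns `gamma`, `se_gamma`.
#' @examples
#' standardizeExposure(0.02, 0.004, 100000)
#' @export
standardizeExposure <- function(beta, se, n) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(n < 2)) stop("sample sizes must be at least 2")
  data.frame(gamma = beta / (se * sqrt(n)), se_gamma = 1 / sqrt(n))
}

#' Standardize an outcome effect
#'
#' Rescales a per-allele outcome effect by the allele-frequency standard
#' deviation: `Gamma = beta * sqrt(2*maf*(1 - maf))` and
#' `se_Gamma = se * sqrt(2*maf*(1 - maf))`. The common factor cancels in
#' the z-score, which is preserved exactly.
#'
#' @param beta per-allele effect estimate(s) (log-odds for a binary
#'   outcome).
#' @param se standard error(s), strictly positive.
#' @param maf minor allele frequency in (0, 0.5\]; monomorphic variants
#'   (maf 0) are rejected.
#' @return data.frame with columns `Gamma`, `se_Gamma`.
#' @export
standardizeOutcome <- function(beta, se, maf) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(maf <= 0 | maf > 0.5))
    stop("maf must lie in (0, 0.5]; monomorphic variants are rejected")
  w <- sqrt(2 * maf * (1 - maf))
  data.frame(Gamma = beta * w, se_Gamma = se * w)
}

#' Standardize harmonized exposure-outcome pairs
#'
#' Applies [standardizeExposure()] and [standardizeOutcome()] to every
#' harmonized pair. The minor allele frequency is `min(eaf, 1 - eaf)` of
#' the outcome record; when the outcome eaf is missing the exposure eaf is
#' substituted with a logged warning. Records with missing or monomorphic
#' frequency, non-positive standard errors, or an exposure sample size
#' below 2 are dropped with counted reasons.
#'
#' @param pairs a [HarmonizedPairs].
#' @return a [StandardizedPairs]; drop counts in attribute `"drop_log"`.
#' @export
standardizePairs <- function(pairs) {
  stopifnot(is(pairs, "HarmonizedPairs"))
  p <- pairs@pairs
  eaf <- p$eaf_out
  substituted <- is.na(eaf) & !is.na(p$eaf_exp)
  eaf[substituted] <- p$eaf_exp[substituted]
  if (any(substituted))
    warning(sprintf("standardizePairs: exposure eaf substituted for %d record(s) with missing outcome eaf",
                    sum(substituted)))
  maf <- pmin(eaf, 1 - eaf)
  ok_maf <- !is.na(maf) & maf > 0 & maf <= 0.5
  ok_se <- p$se_exp > 0 & p$se_out > 0
  ok_n <- p$n_exp >= 2
  ok <- ok_maf & ok_se & ok_n
  drop <- c(monomorphic_or_missing_maf = sum(!ok_maf),
            nonpositive_se = sum(ok_maf & !ok_se),
            small_n = sum(ok_maf & ok_se & !ok_n))
  q <- p[ok, , drop = FALSE]
  expo <- standardizeExposure(q$beta_exp, q$se_exp, q$n_exp)
  outc <- standardizeOutcome(q$beta_out, q$se_out, maf[ok])
  out <- data.frame(snp = q$snp, gamma = expo$gamma, se_gamma = expo$se_gamma,
                    Gamma = outc$Gamma, se_Gamma = outc$se_Gamma,
                    maf = maf[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  res <- new("StandardizedPairs", pairs = out)
  attr(res, "drop_log") <- drop
  res
}

#' Construct standardized pairs from vectors
#'
#' Convenience constructor used by simulations and tests.
#'
#' @param gamma,se_gamma standardized exposure effects and standard errors.
#' @param Gamma,se_Gamma standardized outcome effects and standard errors.
#' @param maf minor allele frequencies in (0, 0.5].
#' @param snp optional ids (default `snp_1..m`).
#' @return a [StandardizedPairs].
#' @export
standardizedPairs <- function(gamma, se_gamma, Gamma, se_Gamma, maf = 0.25,
                              snp = NULL) {
  m <- length(gamma)
  df <- data.frame(
    snp = if (is.null(snp)) sprintf("snp_%d", seq_len(m)) else snp,
    gamma = gamma, se_gamma = rep_len(se_gamma, m),
    Gamma = Gamma, se_Gamma = rep_len(se_Gamma, m),
    maf = rep_len(maf, m), stringsAsFactors = FALSE)
  new("StandardizedPairs", pairs = df)
}

#' Correlation between exposure and outcome effect sizes
#'
#' Pearson correlation of the standardized exposure effects with the
#' standardized outcome effects across instruments, with the large-sample
#' standard error `sqrt((1 - rho^2)/(m - 2))`, plus mean/sd/min/max
#' summaries of each effect-size vector.
#'
#' @param pairs a [StandardizedPairs] with at least 3 instruments.
#' @return an [EffectCorrelation].
#' @export
effectCorrelation <- function(pairs) {
  stopifnot(is(pairs, "StandardizedPairs"))
  p <- pairs@pairs
  m <- nrow(p)
  if (m < 3L)
    stop("effect correlation undefined for fewer than 3 instrument pairs")
  rho <- stats::cor(p$gamma, p$Gamma)
  se <- sqrt((1 - rho^2) / (m - 2))
  summ <- data.frame(
    mean = c(mean(p$gamma), mean(p$Gamma)),
    sd = c(stats::sd(p$gamma), stats::sd(p$Gamma)),
    min = c(min(p$gamma), min(p$Gamma)),
    max = c(max(p$gamma), max(p$Gamma)),
    row.names = c("gamma", "Gamma"))
  new("EffectCorrelation", rho = rho, seRho = se, m = as.integer(m),
      summary = summ)
}

#' Export standardized pairs as TSV
#'
#' Writes `snp, gamma, se_gamma, Gamma, se_Gamma, maf` at full precision
#' for external plotting.
#'
#' @param pairs a [StandardizedPairs].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeStandardizedPairs <- function(pairs, path) {
  stopifnot(is(pairs, "StandardizedPairs"))
  out <- pairs@pairs
  for (col in c("gamma", "se_gamma", "Gamma", "se_Gamma", "maf"))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
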