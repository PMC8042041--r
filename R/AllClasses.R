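#' @import methods
NULL

# canonical column schema shared by every summary-statistic table
.SUMSTAT_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

#' GWAS summary-statistic table
#'
#' One genome-wide association study's per-variant association records on the
#' per-allele scale. Records live in a data.frame with the canonical columns
#' `snp, chr, pos, ea, oa, eaf, beta, se, p, n`. Validity enforces unique
#' variant ids, positive standard errors, allele frequencies in \[0, 1\]
#' (missing allowed), p-values in (0, 1\] and sample sizes of at least one.
#'
#' @slot records data.frame with the canonical columns.
#' @slot traitName character(1), name of the measured trait.
#' @slot traitType `"binary"` or `"quantitative"`; binary traits carry
#'   log-odds effect sizes.
#' @slot ancestry free-text ancestry label.
#'
#' @seealso [readSumstats()], [writeSumstats()], [filterByFrequency()]
#' @export
setClass("SumStats",
  representation(
    records   = "data.frame",
    traitName = "character",
    traitType = "character",
    ancestry  = "character"
  ),
  prototype(
    records   = data.frame(),
    traitName = NA_character_,
    traitType = "quantitative",
    ancestry  = NA_character_
  )
)

setValidity("SumStats", function(object) {
  rec <- object@records
  msg <- character()
  if (nrow(rec) > 0L) {
    missing_cols <- setdiff(.SUMSTAT_COLS, names(rec))
    if (length(missing_cols))
      return(paste("missing canonical columns:", paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(rec$snp))
      msg <- c(msg, "duplicate snp ids")
    if (any(!is.na(rec$se) & rec$se <= 0))
      msg <- c(msg, "non-positive standard errors")
    if (any(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)))
      msg <- c(msg, "eaf outside [0, 1]")
    if (any(!is.na(rec$n) & rec$n < 1))
      msg <- c(msg, "sample size below 1")
    if (any(!is.na(rec$p) & (rec$p <= 0 | rec$p > 1)))
      msg <- c(msg, "p-values outside (0, 1]")
    if (any(rec$ea == rec$oa, na.rm = TRUE))
      msg <- c(msg, "effect allele equals other allele")
  }
  if (!object@traitType %in% c("binary", "quantitative"))
    msg <- c(msg, "traitType must be 'binary' or 'quantitative'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Pairwise linkage-disequilibrium information
#'
#' Squared-correlation lookup between variants together with the genomic
#' coordinates needed for window logic during clumping. Stored as a dense
#' symmetric r-squared matrix over the covered variants; pairs absent from
#' the matrix are treated as independent (r-squared 0) by [ldR2()].
#'
#' @slot snps character vector of covered variant ids (row/column order).
#' @slot r2 numeric matrix of squared correlations, unit diagonal.
#'
#' @seealso [readLDMatrix()], [readLDPairs()], [clumpVariants()]
#' @export
setClass("LDInfo",
  representation(snps = "character", r2 = "matrix"),
  prototype(snps = character(), r2 = matrix(numeric(), 0, 0))
)

setValidity("LDInfo", function(object) {
  m <- object@r2
  if (nrow(m) != length(object@snps) || ncol(m) != length(object@snps))
    return("r2 matrix dimensions do not match snp ids")
  if (length(m)) {
    if (any(m < -1e-8 | m > 1 + 1e-8, na.rm = TRUE))
      return("r2 values outside [0, 1]")
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
      return("r2 matrix not symmetric")
    if (any(abs(diag(m) - 1) > 1e-8, na.rm = TRUE))
      return("r2 diagonal not 1")
  }
  TRUE
})

#' Harmonized exposure-outcome variant pairs
#'
#' Inner join of an exposure and an outcome summary-statistic table with the
#' outcome records re-expressed on the exposure's effect allele. Columns:
#' `snp, chr, pos, ea, oa`, exposure fields (`beta_exp, se_exp, p_exp, n_exp,
#' eaf_exp`), outcome fields (`beta_out, se_out, p_out, n_out, eaf_out`), and
#' the flags `flipped` (outcome alleles were swapped, sign negated) and
#' `palindromic` (A/T or C/G variant).
#'
#' @slot pairs data.frame as described above.
#' @slot log named integer vector of record-drop counts by reason.
#'
#' @seealso [harmonizeSumstats()]
#' @export
setClass("HarmonizedPairs",
  representation(pairs = "data.frame", log = "integer"),
  prototype(pairs = data.frame(), log = integer())
)

setValidity("HarmonizedPairs", function(object) {
  p <- object@pairs
  if (nrow(p) && anyDuplicated(p$snp)) return("duplicate snp ids")
  TRUE
})

#' Standardized instrument effects
#'
#' Per-variant exposure and outcome effects on the unitless standardized
#' scale: `gamma` with `se_gamma = 1/sqrt(n_exposure)` for the exposure and
#' `Gamma` with `se_Gamma` rescaled by the allele-frequency standard
#' deviation for the outcome, plus the minor allele frequency used.
#'
#' @slot pairs data.frame with columns
#'   `snp, gamma, se_gamma, Gamma, se_Gamma, maf`.
#' @seealso [standardizePairs()], [mrIVW()], [mrEgger()], [mrIMRP()], [mrMix()]
#' @export
setClass("StandardizedPairs",
  representation(pairs = "data.frame"),
  prototype(pairs = data.frame())
)

setValidity("StandardizedPairs", function(object) {
  p <- object@pairs
  need <- c("snp", "gamma", "se_gamma", "Gamma", "se_Gamma", "maf")
  if (nrow(p)) {
    miss <- setdiff(need, names(p))
    if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (any(p$se_gamma <= 0) || any(p$se_Gamma <= 0))
      return("non-positive standardized standard errors")
    if (any(p$maf <= 0 | p$maf > 0.5))
      return("maf outside (0, 0.5]")
  }
  TRUE
})

#' Causal-effect estimate
#'
#' Result container shared by every estimator. The causal effect `theta` is
#' on the standardized log-odds scale; `oddsRatio`/`ciLow`/`ciHigh` are its
#' exponentiated point estimate and two-sided 95% confidence limits.
#' Method-specific diagnostics occupy dedicated slots: the Egger intercept
#' triple, the mixture parameters `pi0`/`sigma2` and profile curve, the
#' pruning iteration count, excluded-instrument ids, and a per-variant
#' pleiotropy table where applicable; unused slots hold `NA` / empty values.
#'
#' @slot method one of `"ratio"`, `"IVW"`, `"Egger"`, `"IMRP"`, `"MRMix"`.
#' @slot theta,se,pvalue estimate, standard error, two-sided normal p.
#' @slot oddsRatio,ciLow,ciHigh exp(theta) and its 95% CI.
#' @slot nSNPs number of instruments used in the final estimate.
#' @slot excluded ids of instruments excluded by pruning.
#' @slot intercept,interceptSE,interceptP Egger intercept test.
#' @slot pi0,sigma2 mixture null proportion and pleiotropy variance at the
#'   selected theta.
#' @slot iterations,converged pruning/EM iteration diagnostics.
#' @slot profile data.frame (`theta`, `objective`, `valid`) profile curve.
#' @slot pleiotropy per-variant pleiotropy test table.
#' @slot unstable flat-profile flag (MRMix).
#' @export
setClass("MREstimate",
  representation(
    method      = "character",
    theta       = "numeric",
    se          = "numeric",
    pvalue      = "numeric",
    oddsRatio   = "numeric",
    ciLow       = "numeric",
    ciHigh      = "numeric",
    nSNPs       = "integer",
    excluded    = "character",
    intercept   = "numeric",
    interceptSE = "numeric",
    interceptP  = "numeric",
    pi0         = "numeric",
    sigma2      = "numeric",
    iterations  = "integer",
    converged   = "logical",
    profile     = "data.frame",
    pleiotropy  = "data.frame",
    unstable    = "logical"
  ),
  prototype(
    method = NA_character_, theta = NA_real_, se = NA_real_, pvalue = NA_real_,
    oddsRatio = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
    nSNPs = NA_integer_, excluded = character(),
    intercept = NA_real_, interceptSE = NA_real_, interceptP = NA_real_,
    pi0 = NA_real_, sigma2 = NA_real_,
    iterations = NA_integer_, converged = NA,
    profile = data.frame(), pleiotropy = data.frame(), unstable = FALSE
  )
)

setValidity("MREstimate", function(object) {
  if (!is.na(object@oddsRatio)) {
    if (object@oddsRatio <= 0) return("odds ratio must be positive")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        (object@ciLow > object@oddsRatio + 1e-12 ||
         object@ciHigh < object@oddsRatio - 1e-12))
      return("odds ratio outside its confidence interval")
  }
  TRUE
})

#' Exposure-outcome effect-size correlation summary
#'
#' Pearson correlation between the standardized exposure and outcome effect
#' sizes across instruments, its large-sample standard error
#' `sqrt((1 - rho^2)/(m - 2))`, and per-variable mean/sd/min/max summaries.
#'
#' @slot rho,seRho correlation and its standard error.
#' @slot m number of instrument pairs.
#' @slot summary data.frame (rows `gamma`, `Gamma`; columns
#'   `mean, sd, min, max`).
#' @seealso [effectCorrelation()]
#' @export
setClass("EffectCorrelation",
  representation(rho = "numeric", seRho = "numeric", m = "integer",
                 summary = "data.frame")
)

#' Per-cohort meta-analysis result
#'
#' Fixed-effect inverse-variance combination of several cohorts' summary
#' statistics, with per-variant Cochran heterogeneity diagnostics.
#'
#' @slot table [SumStats] of the combined estimates.
#' @slot perVariant data.frame with `snp, k, Q, Q_pvalue, het_flag`;
#'   `Q` is `NA` for variants present in a single study.
#' @slot hetAlpha nominal heterogeneity test size before the Bonferroni
#'   division by the number of variants tested.
#' @seealso [metaAnalyze()]
#' @export
setClass("MetaAnalysis",
  representation(table = "SumStats", perVariant = "data.frame",
                 hetAlpha = "numeric")
)
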