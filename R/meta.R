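#' Fixed-effect inverse-variance meta-analysis of GWAS cohorts
#'
#' Combines per-cohort summary statistics variant-by-variant with
#' inverse-variance weights:
#' `beta_meta = sum(beta_k/se_k^2) / sum(1/se_k^2)`,
#' `se_meta = sum(1/se_k^2)^(-1/2)`, two-sided p from the normal ratio, and
#' Cochran's `Q = sum((beta_k - beta_meta)^2 / se_k^2)` on `k - 1` degrees
#' of freedom. A variant is flagged heterogeneous when its Q p-value falls
#' below `het_alpha` divided by the number of variants tested with at least
#' two studies (Bonferroni). Flagged variants are retained but reported.
#'
#' Cohorts after the first are aligned to the first cohort's effect allele:
#' swapped alleles sign-flip the beta and mirror the frequency; strand
#' complements are attempted next; variants whose alleles cannot be
#' reconciled are excluded from that cohort's contribution and counted in
#' the `"drop_log"` attribute. Variants present in a single cohort pass
#' through unchanged with `Q = NA` and `het_flag = FALSE`. Meta sample size
#' is the sum of contributing cohort sizes; meta eaf is their n-weighted
#' mean.
#'
#' @param tables list of [SumStats] objects (one per cohort).
#' @param het_alpha nominal heterogeneity test size before Bonferroni
#'   division (default 0.05).
#' @return a [MetaAnalysis]; `table` slot holds the combined [SumStats],
#'   `perVariant` the heterogeneity diagnostics.
#' @examples
#' rec <- data.frame(snp = "rs1", chr = "1", pos = 100L, ea = "A", oa = "G",
#'                   eaf = 0.3, beta = 0.1, se = 0.1, p = 0.32, n = 1000)
#' s1 <- pleioMR:::.sumstats(rec)
#' rec$beta <- 0.3
#' s2 <- pleioMR:::.sumstats(rec)
#' metaAnalyze(list(s1, s2))
#' @export
metaAnalyze <- function(tables, het_alpha = 0.05) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, is, TRUE, "SumStats")),
            het_alpha > 0, het_alpha <= 1)
  base <- tables[[1L]]@records
  k_tab <- length(tables)
  dropped_alleles <- 0L

  # per-variant accumulators keyed by the first table's rows; variants absent
  # from the first cohort are appended in encounter order
  all_snps <- base$snp
  for (tb in tables[-1L])
    all_snps <- c(all_snps, setdiff(tb@records$snp, all_snps))
  m <- length(all_snps)
  ref <- data.frame(snp = all_snps, chr = NA_character_, pos = NA_integer_,
                    ea = NA_character_, oa = NA_character_,
                    stringsAsFactors = FALSE)
  w_sum <- numeric(m); bw_sum <- numeric(m); n_sum <- numeric(m)
  eafn_sum <- numeric(m); eafn_w <- numeric(m); k_cnt <- integer(m)
  betas <- matrix(NA_real_, m, k_tab)
  ses   <- matrix(NA_real_, m, k_tab)

  for (j in seq_len(k_tab)) {
    rec <- tables[[j]]@records
    idx <- match(rec$snp, ref$snp)
    newref <- is.na(ref$ea[idx])
    ref$chr[idx[newref]] <- rec$chr[newref]
    ref$pos[idx[newref]] <- rec$pos[newref]
    ref$ea[idx[newref]] <- rec$ea[newref]
    ref$oa[idx[newref]] <- rec$oa[newref]
    ali <- .alignAlleles(rec$ea, rec$oa, ref$ea[idx], ref$oa[idx])
    drop <- is.na(ali)
    dropped_alleles <- dropped_alleles + sum(drop)
    keep <- which(!drop)
    if (!length(keep)) next
    i <- idx[keep]
    sgn <- ifelse(ali[keep], -1, 1)   # TRUE = swapped -> flip sign
    b <- sgn * rec$beta[keep]
    eaf <- ifelse(ali[keep], 1 - rec$eaf[keep], rec$eaf[keep])
    w <- 1 / rec$se[keep]^2
    w_sum[i] <- w_sum[i] + w
    bw_sum[i] <- bw_sum[i] + w * b
    n_sum[i] <- n_sum[i] + rec$n[keep]
    has_eaf <- !is.na(eaf)
    eafn_sum[i[has_eaf]] <- eafn_sum[i[has_eaf]] +
      eaf[has_eaf] * rec$n[keep][has_eaf]
    eafn_w[i[has_eaf]] <- eafn_w[i[has_eaf]] + rec$n[keep][has_eaf]
    k_cnt[i] <- k_cnt[i] + 1L
    betas[cbind(i, j)] <- b
    ses[cbind(i, j)] <- rec$se[keep]
  }

  present <- k_cnt >= 1L
  beta_meta <- bw_sum / w_sum
  se_meta <- 1 / sqrt(w_sum)
  p_meta <- 2 * stats::pnorm(-abs(beta_meta / se_meta))
  p_meta <- pmax(p_meta, .Machine$double.xmin)
  Q <- rowSums((betas - beta_meta)^2 / ses^2, na.rm = TRUE)
  Q[k_cnt < 2L] <- NA_real_
  Qp <- ifelse(is.na(Q), NA_real_,
               stats::pchisq(Q, df = pmax(k_cnt - 1L, 1L), lower.tail = FALSE))
  n_tested <- sum(k_cnt >= 2L)
  het_flag <- !is.na(Qp) & n_tested > 0L & Qp < het_alpha / max(n_tested, 1L)

  rec_out <- data.frame(
    snp = ref$snp, chr = ref$chr, pos = ref$pos, ea = ref$ea, oa = ref$oa,
    eaf = ifelse(eafn_w > 0, eafn_sum / eafn_w, NA_real_),
    beta = beta_meta, se = se_meta, p = p_meta, n = n_sum,
    stringsAsFactors = FALSE
  )[present, , drop = FALSE]
  if (dropped_alleles)
    message(sprintf("metaAnalyze: excluded %d cohort record(s) with unreconcilable alleles",
                    dropped_alleles))
  tab <- .sumstats(rec_out, trait_name = tables[[1L]]@traitName,
                   trait_type = tables[[1L]]@traitType,
                   ancestry = tables[[1L]]@ancestry)
  attr(tab, "drop_log") <- c(unreconcilable_alleles = dropped_alleles)
  pv <- data.frame(snp = ref$snp, k = k_cnt, Q = Q, Q_pvalue = Qp,
                   het_flag = het_flag,
                   stringsAsFactors = FALSE)[present, , drop = FALSE]
  rownames(pv) <- NULL
  new("MetaAnalysis", table = tab, perVariant = pv, hetAlpha = het_alpha)
}

# Align (ea, oa) to reference (ref_ea, ref_oa).
# Returns FALSE = already aligned, TRUE = swapped (sign flip needed),
# NA = unreconcilable. Strand complements are tried for pure ACGT alleles.
.alignAlleles <- function(ea, oa, ref_ea, ref_oa) {
  out <- rep(NA, length(ea))
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  out[same] <- FALSE
  out[swap & !same] <- TRUE
  todo <- is.na(out)
  if (any(todo)) {
    cea <- .strandComplement(ea[todo]); coa <- .strandComplement(oa[todo])
    same2 <- !is.na(cea) & !is.na(coa) & cea == ref_ea[todo] & coa == ref_oa[todo]
    swap2 <- !is.na(cea) & !is.na(coa) & cea == ref_oa[todo] & coa == ref_ea[todo]
    sub <- rep(NA, sum(todo))
    sub[same2] <- FALSE
    sub[swap2 & !same2] <- TRUE
    out[todo] <- sub
  }
  out
}

# reverse complement; NA for alleles outside the ACGT alphabet (indels and
# multi-allelic codes are not strand-resolvable)
.strandComplement <- function(x) {
  ok <- grepl("^[ACGT]+$", x)
  out <- rep(NA_character_, length(x))
  out[ok] <- toupper(chartr("ACGT", "TGCA", vapply(x[ok], function(s)
    paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1L),
    USE.NAMES = FALSE)))
  out
}
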