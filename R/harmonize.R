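#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins two [SumStats] tables by variant id and re-expresses the
#' outcome records on the exposure's effect allele. Matching proceeds in
#' order: identical allele pair (kept as-is); swapped pair (outcome beta
#' negated, eaf mirrored, `flipped = TRUE`); strand complement of the
#' outcome alleles, identical or swapped. Variants whose alleles cannot be
#' reconciled are dropped and counted.
#'
#' Palindromic variants (effect allele is the strand complement of the other
#' allele, i.e. A/T or C/G) are ambiguous under a strand flip and are
#' handled per `palindromic`:
#' \describe{
#'   \item{`"infer"`}{(default) keep when both studies' minor-allele
#'     frequencies are below 0.4 and point at the same allele, flipping when
#'     the effect-allele frequencies sit on opposite sides of 0.5; drop when
#'     either frequency is too close to 0.5 to call, or missing.}
#'   \item{`"drop"`}{drop all palindromic variants.}
#'   \item{`"keep"`}{keep them, trusting the reported strands.}
#' }
#'
#' @param exposure,outcome validated [SumStats] objects.
#' @param palindromic policy, one of `"infer"`, `"drop"`, `"keep"`.
#' @param freq_limit inference limit on the minor-allele frequency for the
#'   `"infer"` policy (default 0.4).
#' @return a [HarmonizedPairs]; the `log` slot counts drops by reason.
#' @export
harmonizeSumstats <- function(exposure, outcome,
                              palindromic = c("infer", "drop", "keep"),
                              freq_limit = 0.4) {
  stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"))
  palindromic <- match.arg(palindromic)
  ex <- exposure@records
  ou <- outcome@records
  idx <- match(ex$snp, ou$snp)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no shared variant ids between exposure and outcome tables; ",
         "check id formats (e.g. rsID vs chr:pos)")
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[idx[keep], , drop = FALSE]
  m <- nrow(ex)

  pal <- .isPalindromic(ex$ea, ex$oa)
  flipped <- rep(FALSE, m)
  drop_reason <- rep(NA_character_, m)

  # non-palindromic: direct / swapped / strand-complement matching
  np <- which(!pal)
  if (length(np)) {
    ali <- .alignAlleles(ou$ea[np], ou$oa[np], ex$ea[np], ex$oa[np])
    drop_reason[np[is.na(ali)]] <- "unreconcilable_alleles"
    flipped[np] <- !is.na(ali) & ali
  }
  # palindromic: complement equals swap, so allele labels cannot resolve
  # strand; use the configured policy
  pp <- which(pal)
  if (length(pp)) {
    if (palindromic == "drop") {
      drop_reason[pp] <- "palindromic_dropped"
    } else {
      labels_match <- (ou$ea[pp] == ex$ea[pp] & ou$oa[pp] == ex$oa[pp]) |
                      (ou$ea[pp] == ex$oa[pp] & ou$oa[pp] == ex$ea[pp])
      drop_reason[pp[!labels_match]] <- "unreconcilable_alleles"
      pp <- pp[labels_match]
      if (palindromic == "keep") {
        flipped[pp] <- ou$ea[pp] == ex$oa[pp]
      } else {  # infer from allele frequency
        fe <- ex$eaf[pp]; fo <- ou$eaf[pp]
        inferable <- !is.na(fe) & !is.na(fo) &
          pmin(fe, 1 - fe) < freq_limit & pmin(fo, 1 - fo) < freq_limit
        drop_reason[pp[!inferable]] <- "palindromic_ambiguous"
        same_side <- (fe < 0.5) == (fo < 0.5)
        flipped[pp] <- inferable & !same_side
      }
    }
  }

  ok <- is.na(drop_reason)
  log <- table(factor(drop_reason[!ok],
                      levels = c("unreconcilable_alleles",
                                 "palindromic_dropped",
                                 "palindromic_ambiguous")))
  log <- stats::setNames(as.integer(log), names(log))
  ex <- ex[ok, , drop = FALSE]; ou <- ou[ok, , drop = FALSE]
  fl <- flipped[ok]
  pairs <- data.frame(
    snp = ex$snp, chr = ex$chr, pos = ex$pos, ea = ex$ea, oa = ex$oa,
    beta_exp = ex$beta, se_exp = ex$se, p_exp = ex$p, n_exp = ex$n,
    eaf_exp = ex$eaf,
    beta_out = ifelse(fl, -ou$beta, ou$beta),
    se_out = ou$se, p_out = ou$p, n_out = ou$n,
    eaf_out = ifelse(fl, 1 - ou$eaf, ou$eaf),
    flipped = fl, palindromic = pal[ok],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  if (sum(log))
    message(sprintf("harmonizeSumstats: dropped %d variant(s) [%s]", sum(log),
                    paste(sprintf("%s=%d", names(log)[log > 0], log[log > 0]),
                          collapse = ", ")))
  new("HarmonizedPairs", pairs = pairs, log = log)
}

.isPalindromic <- function(ea, oa) {
  comp <- .strandComplement(ea)
  !is.na(comp) & comp == oa
}
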