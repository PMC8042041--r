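#' Greedy LD clumping of significant variants
#'
#' Selects approximately independent genome-wide-significant index variants
#' the way PLINK's `--clump` does: variants with `p < p1` are sorted by
#' ascending p-value (ties broken by lexicographic variant id); the best
#' remaining variant becomes an index SNP and every remaining candidate on
#' the same chromosome within `window_kb` kilobases whose squared
#' correlation with it is at least `r2_max` is removed; this repeats until
#' no candidates remain. Pairs absent from the LD reference count as
#' independent (see [ldR2()]). The result is invariant to input row order.
#'
#' @param x a [SumStats], [HarmonizedPairs] (exposure p-values are used) or
#'   data.frame with columns `snp, chr, pos` and `p` (or `p_exp`).
#' @param ld an [LDInfo] covering the candidate variants.
#' @param p1 index-variant significance threshold (default 5e-8).
#' @param r2_max squared-correlation threshold at or above which a
#'   neighbour is clumped away (default 0.1; sensitivity analyses commonly
#'   use 0.05).
#' @param window_kb physical window in kilobases (default 500).
#' @return character vector of selected index variant ids, in selection
#'   order (empty when nothing passes `p1`).
#' @export
clumpVariants <- function(x, ld, p1 = 5e-8, r2_max = 0.1, window_kb = 500) {
  stopifnot(is(ld, "LDInfo"), p1 > 0, r2_max > 0, window_kb > 0)
  df <- if (is(x, "SumStats")) x@records
        else if (is(x, "HarmonizedPairs")) x@pairs
        else x
  pcol <- if ("p" %in% names(df)) "p" else if ("p_exp" %in% names(df)) "p_exp"
          else stop("no p-value column found")
  cand <- data.frame(snp = as.character(df$snp), chr = as.character(df$chr),
                     pos = as.numeric(df$pos), p = df[[pcol]],
                     stringsAsFactors = FALSE)
  cand <- cand[cand$p < p1, , drop = FALSE]
  if (nrow(cand) == 0L) return(character())
  cand <- cand[order(cand$p, cand$snp), , drop = FALSE]
  selected <- character()
  active <- rep(TRUE, nrow(cand))
  missing_pairs <- 0L
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    active[i] <- FALSE
    selected <- c(selected, cand$snp[i])
    rest <- which(active)
    if (!length(rest)) next
    near <- rest[cand$chr[rest] == cand$chr[i] &
                 abs(cand$pos[rest] - cand$pos[i]) <= window_kb * 1000]
    if (!length(near)) next
    r2 <- withCallingHandlers(
      ldR2(ld, cand$snp[i], cand$snp[near]),
      warning = function(w) {
        if (grepl("missing from the LD reference", conditionMessage(w))) {
          missing_pairs <<- missing_pairs +
            as.integer(sub(".*?(\\d+) pair.*", "\\1", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      })
    active[near[r2 >= r2_max]] <- FALSE
  }
  if (missing_pairs)
    warning(sprintf("clumpVariants: %d LD pair(s) missing from the reference treated as independent",
                    missing_pairs))
  selected
}
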