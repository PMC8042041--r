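#' Number of variants in a container
#' @param x a [SumStats], [HarmonizedPairs] or [StandardizedPairs] object.
#' @return integer(1).
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' Variant identifiers
#' @param x a [SumStats], [HarmonizedPairs], [StandardizedPairs] or [LDInfo]
#'   object.
#' @return character vector of snp ids in storage order.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' Underlying records as a data.frame
#' @param x a container object.
#' @return the data.frame held by the object, unmodified.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Causal-effect point estimate
#' @param object an [MREstimate].
#' @return numeric(1), theta on the standardized (log-odds) scale.
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))

#' Standard error of the causal-effect estimate
#' @param object an [MREstimate].
#' @return numeric(1).
#' @export
setGeneric("seTheta", function(object) standardGeneric("seTheta"))

#' Odds ratio with 95% confidence interval
#' @param object an [MREstimate].
#' @return named numeric: `or`, `ci_low`, `ci_high`.
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' Two-sided p-value of an estimate
#' @param object an [MREstimate].
#' @return numeric(1).
#' @export
setGeneric("pvalue", function(object) standardGeneric("pvalue"))

#' @describeIn nVariants rows of the records table
#' @export
setMethod("nVariants", "SumStats", function(x) nrow(x@records))

#' @describeIn nVariants harmonized pair count
#' @export
setMethod("nVariants", "HarmonizedPairs", function(x) nrow(x@pairs))

#' @describeIn nVariants standardized pair count
#' @export
setMethod("nVariants", "StandardizedPairs", function(x) nrow(x@pairs))

#' @describeIn variantIds ids of a summary-statistic table
#' @export
setMethod("variantIds", "SumStats", function(x) as.character(x@records$snp))

#' @describeIn variantIds ids of harmonized pairs
#' @export
setMethod("variantIds", "HarmonizedPairs", function(x) as.character(x@pairs$snp))

#' @describeIn variantIds ids of standardized pairs
#' @export
setMethod("variantIds", "StandardizedPairs", function(x) as.character(x@pairs$snp))

#' @describeIn variantIds ids covered by an LD lookup
#' @export
setMethod("variantIds", "LDInfo", function(x) x@snps)

#' @describeIn records summary-statistic records
#' @export
setMethod("records", "SumStats", function(x) x@records)

#' @describeIn records harmonized pair table
#' @export
setMethod("records", "HarmonizedPairs", function(x) x@pairs)

#' @describeIn records standardized pair table
#' @export
setMethod("records", "StandardizedPairs", function(x) x@pairs)

#' @describeIn theta point estimate
#' @export
setMethod("theta", "MREstimate", function(object) object@theta)

#' @describeIn seTheta standard error
#' @export
setMethod("seTheta", "MREstimate", function(object) object@se)

#' @describeIn pvalue two-sided normal p
#' @export
setMethod("pvalue", "MREstimate", function(object) object@pvalue)

#' @describeIn oddsRatio exponentiated estimate and 95% CI
#' @export
setMethod("oddsRatio", "MREstimate", function(object)
  c(or = object@oddsRatio, ci_low = object@ciLow, ci_high = object@ciHigh))

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats: %s (%s, %s)\n",
              object@traitName, object@traitType,
              ifelse(is.na(object@ancestry), "unspecified ancestry",
                     object@ancestry)))
  cat(sprintf("  %d variants\n", nrow(object@records)))
  if (nrow(object@records)) {
    cat("  head:\n")
    print(utils::head(object@records, 3L))
  }
  invisible(NULL)
})

setMethod("show", "LDInfo", function(object) {
  cat(sprintf("LDInfo: %d variants, %d pairwise r2 values\n",
              length(object@snps),
              length(object@snps) * (length(object@snps) - 1L) / 2L))
  invisible(NULL)
})

setMethod("show", "HarmonizedPairs", function(object) {
  cat(sprintf("HarmonizedPairs: %d variants (%d flipped, %d palindromic)\n",
              nrow(object@pairs),
              sum(object@pairs$flipped %||% logical()),
              sum(object@pairs$palindromic %||% logical())))
  if (length(object@log) && sum(object@log))
    cat("  dropped:", paste(sprintf("%s=%d", names(object@log), object@log),
                            collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "StandardizedPairs", function(object) {
  cat(sprintf("StandardizedPairs: %d instruments\n", nrow(object@pairs)))
  if (nrow(object@pairs)) {
    cat(sprintf("  gamma in [%.4g, %.4g]; Gamma in [%.4g, %.4g]\n",
                min(object@pairs$gamma), max(object@pairs$gamma),
                min(object@pairs$Gamma), max(object@pairs$Gamma)))
  }
  invisible(NULL)
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]\n", object@method))
  cat(sprintf("  theta = %.4f (se %.4f), p = %.3g\n",
              object@theta, object@se, object@pvalue))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), %d instruments\n",
              object@oddsRatio, object@ciLow, object@ciHigh, object@nSNPs))
  if (object@method == "Egger")
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                object@intercept, object@interceptSE, object@interceptP))
  if (object@method == "IMRP")
    cat(sprintf("  %d excluded in %d iteration(s)%s\n",
                length(object@excluded), object@iterations,
                if (isFALSE(object@converged)) " [not converged]" else ""))
  if (object@method == "MRMix")
    cat(sprintf("  pi0 = %.3f, sigma2 = %.3g%s\n", object@pi0, object@sigma2,
                if (isTRUE(object@unstable)) " [flat profile: unstable]" else ""))
  invisible(NULL)
})

setMethod("show", "EffectCorrelation", function(object) {
  cat(sprintf("EffectCorrelation: rho = %.3f (se %.3f), m = %d\n",
              object@rho, object@seRho, object@m))
  print(object@summary)
  invisible(NULL)
})

setMethod("show", "MetaAnalysis", function(object) {
  pv <- object@perVariant
  cat(sprintf("MetaAnalysis: %d variants, up to %d studies\n",
              nrow(pv), if (nrow(pv)) max(pv$k) else 0L))
  cat(sprintf("  heterogeneity flagged (Bonferroni): %d\n",
              sum(pv$het_flag, na.rm = TRUE)))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
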