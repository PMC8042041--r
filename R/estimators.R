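CI_Z <- 1.959964  # two-sided 95% normal multiplier

# assemble an MREstimate with OR fields populated
.mrEstimate <- function(method, theta, se, nSNPs, ...) {
  orci <- toOddsRatio(theta, se)
  p <- if (is.na(se) || se == 0) {
    if (!is.na(theta) && theta == 0) 1 else NA_real_
  } else max(2 * stats::pnorm(-abs(theta / se)), .Machine$double.xmin)
  new("MREstimate", method = method, theta = theta, se = se, pvalue = p,
      oddsRatio = orci[["or"]], ciLow = orci[["ci_low"]],
      ciHigh = orci[["ci_high"]], nSNPs = as.integer(nSNPs), ...)
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' `OR = exp(theta)`, `CI = exp(theta +/- 1.959964 * se)`.
#'
#' @param theta effect on the log-odds scale.
#' @param se its standard error, non-negative.
#' @return named numeric: `or`, `ci_low`, `ci_high`.
#' @examples
#' toOddsRatio(0.5, 0.1)
#' @export
toOddsRatio <- function(theta, se) {
  stopifnot(is.na(se) || se >= 0)
  c(or = exp(theta), ci_low = exp(theta - CI_Z * se),
    ci_high = exp(theta + CI_Z * se))
}

#' Wald ratio estimate from a single instrument
#'
#' Per-variant causal estimate `theta = Gamma / gamma` with the first-order
#' delta-method standard error
#' `sqrt(se_Gamma^2/gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)`.
#'
#' @param pair a [StandardizedPairs] with exactly one instrument, or a
#'   one-row data.frame with columns `gamma, se_gamma, Gamma, se_Gamma`.
#' @return an [MREstimate] with method `"ratio"`.
#' @export
mrWaldRatio <- function(pair) {
  p <- if (is(pair, "StandardizedPairs")) pair@pairs else pair
  stopifnot(nrow(p) == 1L)
  if (p$gamma == 0)
    stop("Wald ratio undefined: instrument has zero exposure effect")
  th <- p$Gamma / p$gamma
  se <- sqrt(p$se_Gamma^2 / p$gamma^2 +
             p$Gamma^2 * p$se_gamma^2 / p$gamma^4)
  .mrEstimate("ratio", th, se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least squares of the standardized outcome effects on the
#' standardized exposure effects through the origin, with fixed-effect
#' weights `1/se_Gamma^2`:
#' `theta = sum(w * gamma * Gamma) / sum(w * gamma^2)`,
#' `se = sum(w * gamma^2)^(-1/2)`. With
#' `weighting = "random"`, the standard error is inflated by
#' `max(1, sqrt(Q/(m - 1)))` (multiplicative random effects). With one
#' instrument the estimate collapses to the Wald ratio.
#'
#' @param pairs a [StandardizedPairs] with at least one instrument with a
#'   nonzero exposure effect.
#' @param weighting `"fixed"` (default) or `"random"`.
#' @return an [MREstimate] with method `"IVW"`.
#' @export
mrIVW <- function(pairs, weighting = c("fixed", "random")) {
  weighting <- match.arg(weighting)
  p <- if (is(pairs, "StandardizedPairs")) pairs@pairs else pairs
  if (nrow(p) < 1L || all(p$gamma == 0))
    stop("IVW undefined: no instrument with nonzero exposure effect")
  w <- 1 / p$se_Gamma^2
  sxx <- sum(w * p$gamma^2)
  th <- sum(w * p$gamma * p$Gamma) / sxx
  se <- 1 / sqrt(sxx)
  if (weighting == "random" && nrow(p) > 1L) {
    Q <- sum(w * (p$Gamma - th * p$gamma)^2)
    se <- se * max(1, sqrt(Q / (nrow(p) - 1L)))
  }
  .mrEstimate("IVW", th, se, nrow(p))
}

#' MR-Egger regression
#'
#' Weighted least squares of the standardized outcome effects on the
#' standardized exposure effects with an intercept, weights `1/se_Gamma^2`.
#' The slope estimates the causal effect under the InSIDE assumption; the
#' intercept estimates the mean directional pleiotropy and its two-sided
#' normal test is reported as the pleiotropy diagnostic. By default
#' instruments are first oriented so every exposure effect is non-negative
#' (the conventional Egger orientation, under which the intercept is
#' identified); set `orient = FALSE` to regress on the signed effects.
#'
#' @param pairs a [StandardizedPairs] with at least 3 instruments.
#' @param orient logical; flip (gamma, Gamma) signs so gamma >= 0.
#' @return an [MREstimate] with method `"Egger"`, intercept slots filled.
#' @export
mrEgger <- function(pairs, orient = TRUE) {
  p <- if (is(pairs, "StandardizedPairs")) pairs@pairs else pairs
  if (nrow(p) < 3L)
    stop("MR-Egger needs at least 3 instruments")
  g <- p$gamma; G <- p$Gamma
  if (orient) {
    s <- ifelse(g < 0, -1, 1)
    g <- s * g; G <- s * G
  }
  w <- 1 / p$se_Gamma^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); sx <- sum(w * g); sxx <- sum(w * g^2)
  sy <- sum(w * G); sxy <- sum(w * g * G)
  det <- sw * sxx - sx^2
  if (det <= 0)
    stop("MR-Egger design is singular (no spread in exposure effects)")
  slope <- (sw * sxy - sx * sy) / det
  inter <- (sxx * sy - sx * sxy) / det
  var_slope <- sw / det
  var_inter <- sxx / det
  inter_se <- sqrt(var_inter)
  inter_p <- max(2 * stats::pnorm(-abs(inter / inter_se)),
                 .Machine$double.xmin)
  .mrEstimate("Egger", slope, sqrt(var_slope), nrow(p),
              intercept = inter, interceptSE = inter_se, interceptP = inter_p)
}

#' Per-variant horizontal-pleiotropy test
#'
#' Tests whether a variant's outcome effect deviates from what its exposure
#' effect transmits through the causal path, at a given causal effect:
#' `t = (Gamma - theta*gamma) /
#'   sqrt(se_Gamma^2 + theta^2*se_gamma^2 -
#'        2*theta*rho_overlap*se_Gamma*se_gamma)`
#' with a two-sided normal p-value. `rho_overlap` is the correlation between
#' the exposure and outcome estimate errors induced by shared samples; the
#' cross term corrects the residual variance for it. Nominal flags use
#' p < 0.05 and Bonferroni flags p < 0.05/m over the m variants tested.
#'
#' @param pairs a [StandardizedPairs] (all variants are tested).
#' @param theta causal effect at which to test.
#' @param rho_overlap sample-overlap correlation in (-1, 1), default 0.
#' @param alpha nominal flag level (default 0.05).
#' @return data.frame with columns
#'   `snp, t_stat, pvalue, flagged_nominal, flagged_bonferroni`.
#' @export
mrPleiotropyTest <- function(pairs, theta, rho_overlap = 0, alpha = 0.05) {
  p <- if (is(pairs, "StandardizedPairs")) pairs@pairs else pairs
  stopifnot(abs(rho_overlap) < 1)
  v <- p$se_Gamma^2 + theta^2 * p$se_gamma^2 -
       2 * theta * rho_overlap * p$se_Gamma * p$se_gamma
  if (any(v <= 0))
    stop("non-positive residual variance; rho_overlap is inconsistent with the standard errors")
  t <- (p$Gamma - theta * p$gamma) / sqrt(v)
  pv <- pmax(2 * stats::pnorm(-abs(t)), .Machine$double.xmin)
  m <- nrow(p)
  data.frame(snp = p$snp, t_stat = t, pvalue = pv,
             flagged_nominal = pv < alpha,
             flagged_bonferroni = pv < alpha / m,
             stringsAsFactors = FALSE)
}

#' Iterative causal estimation with pleiotropy pruning
#'
#' Alternates causal-effect estimation and per-variant pleiotropy testing:
#' starting from the IVW estimate on all instruments, each iteration (1)
#' tests every instrument at the current estimate with
#' [mrPleiotropyTest()], (2) excludes those with p below `alpha_pleio`, and
#' (3) re-estimates the effect on the retained set by weighted least
#' squares through the origin with the overlap-corrected inverse-variance
#' weights `1/(se_Gamma^2 + theta^2*se_gamma^2 -
#' 2*theta*rho_overlap*se_Gamma*se_gamma)`. Iteration stops when the
#' excluded set is unchanged (a fixed point) or `max_iter` is reached.
#' `alpha_pleio = 0` disables exclusion and reproduces IVW exactly.
#'
#' @param pairs a [StandardizedPairs] with at least 3 instruments.
#' @param alpha_pleio per-variant exclusion threshold (default 0.05).
#' @param rho_overlap sample-overlap correlation in (-1, 1), default 0.
#' @param max_iter iteration cap (default 50).
#' @return an [MREstimate] with method `"IMRP"`; the final per-variant test
#'   table sits in the `pleiotropy` slot and excluded ids in `excluded`.
#' @export
mrIMRP <- function(pairs, alpha_pleio = 0.05, rho_overlap = 0, max_iter = 50L) {
  p <- if (is(pairs, "StandardizedPairs")) pairs@pairs else pairs
  if (nrow(p) < 3L) stop("iterative pruning needs at least 3 instruments")
  stopifnot(alpha_pleio >= 0, alpha_pleio < 1, abs(rho_overlap) < 1,
            max_iter >= 1L)
  if (alpha_pleio == 0) {
    # threshold disables exclusion entirely: identical to IVW
    ivw <- mrIVW(p)
    return(.mrEstimate("IMRP", ivw@theta, ivw@se, nrow(p),
                       excluded = character(), iterations = 1L,
                       converged = TRUE,
                       pleiotropy = mrPleiotropyTest(p, ivw@theta,
                                                     rho_overlap)))
  }
  est_on <- function(q, th_for_w) {
    v <- q$se_Gamma^2 + th_for_w^2 * q$se_gamma^2 -
         2 * th_for_w * rho_overlap * q$se_Gamma * q$se_gamma
    if (any(v <= 0))
      stop("non-positive weight variance under the overlap correction")
    w <- 1 / v
    sxx <- sum(w * q$gamma^2)
    list(theta = sum(w * q$gamma * q$Gamma) / sxx, se = 1 / sqrt(sxx))
  }
  th <- mrIVW(p)@theta
  excluded <- rep(FALSE, nrow(p))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pt <- mrPleiotropyTest(p, th, rho_overlap)
    new_excl <- if (alpha_pleio > 0) pt$pvalue < alpha_pleio
                else rep(FALSE, nrow(p))
    if (all(new_excl)) stop("all instruments excluded as pleiotropic")
    fit <- est_on(p[!new_excl, , drop = FALSE], th)
    th <- fit$theta
    if (identical(new_excl, excluded)) { converged <- TRUE; excluded <- new_excl; break }
    excluded <- new_excl
    if (iter >= max_iter) break
  }
  fit <- est_on(p[!excluded, , drop = FALSE], th)
  if (!converged)
    warning("iterative pruning did not converge within max_iter; returning last iterate")
  .mrEstimate("IMRP", fit$theta, fit$se, sum(!excluded),
              excluded = as.character(p$snp[excluded]),
              iterations = iter, converged = converged, pleiotropy = pt)
}
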