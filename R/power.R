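#' Approximate power of the IVW causal test for a binary outcome
#'
#' Two-sided normal (noncentrality) approximation. The noncentrality
#' parameter is
#' `ncp = theta * sqrt(n_outcome * r2_instrument * case_fraction *
#'   (1 - case_fraction))`
#' and the power at test size `alpha` is
#' `pnorm(-z + |ncp|) + pnorm(-z - |ncp|)` with `z = qnorm(1 - alpha/2)`.
#' At `theta = 0` the power equals `alpha` exactly, and it is monotone
#' non-decreasing in `|theta|`, `n_outcome` and `r2_instrument`. This is an
#' analytic approximation; simulation-based power is available by running
#' the estimators on [simulateMRData()] output.
#'
#' @param theta assumed causal effect (log-odds per exposure SD).
#' @param r2_instrument proportion of exposure variance explained by the
#'   instruments, in \[0, 1\].
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction proportion of cases in the outcome GWAS, in (0, 1).
#' @param alpha two-sided test size in (0, 1), default 0.05.
#' @return data.frame with columns
#'   `power, alpha, n_outcome, case_fraction, r2_instrument, theta`
#'   (vectorized over the inputs).
#' @examples
#' mrPower(theta = 0.26, r2_instrument = 0.02, n_outcome = 10908,
#'         case_fraction = 2430 / 10808)
#' @export
mrPower <- function(theta, r2_instrument, n_outcome, case_fraction,
                    alpha = 0.05) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  if (any(case_fraction <= 0 | case_fraction >= 1))
    stop("case_fraction must lie in (0, 1)")
  if (any(r2_instrument < 0 | r2_instrument > 1))
    stop("r2_instrument must lie in [0, 1]")
  if (any(n_outcome < 1)) stop("n_outcome must be at least 1")
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- theta * sqrt(n_outcome * r2_instrument * case_fraction *
                        (1 - case_fraction))
  pow <- stats::pnorm(-z + abs(ncp)) + stats::pnorm(-z - abs(ncp))
  data.frame(power = pow, alpha = alpha, n_outcome = n_outcome,
             case_fraction = case_fraction, r2_instrument = r2_instrument,
             theta = theta)
}
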