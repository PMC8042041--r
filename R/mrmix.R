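#' Normal-mixture causal-effect estimation (profile search)
#'
#' Estimates the causal effect by profiling a two-component normal mixture
#' over a grid of candidate effects. At each candidate `theta` the residuals
#' `d_i = Gamma_i - theta*gamma_i` have known null variance
#' `s_i^2 = se_Gamma_i^2 + theta^2*se_gamma_i^2`; the mixture
#' `pi0*N(0, s_i^2) + (1 - pi0)*N(0, s_i^2 + sigma2)` is fitted by
#' expectation-maximization with unknown null proportion `pi0` and
#' pleiotropy variance `sigma2`. The profile objective is the fitted `pi0`:
#' at the true effect the residuals of all valid instruments are pure
#' noise, so `pi0` peaks there. The estimate is the grid argmax (ties go to
#' the smaller `|theta|`); the standard error comes from a nonparametric
#' bootstrap over instruments.
#'
#' The `sigma2` update uses the closed-form hierarchical EM step (latent
#' per-variant pleiotropy effect with conditional variance
#' `sigma2*s_i^2/(sigma2 + s_i^2)`), vectorized across the whole grid.
#' `sigma2` is floored at `1e-12` to prevent component collapse and `pi0`
#' starts at 0.9. Grid points whose EM fails to converge are marked invalid
#' and skipped with a warning. A profile whose objective range falls below
#' `flat_tol` is flagged unstable (wide-confidence-interval regime).
#'
#' @param pairs a [StandardizedPairs] with at least 10 instruments.
#' @param theta_grid ordered candidate effects (default `seq(-2, 2, 0.01)`).
#' @param em_tol EM convergence tolerance on parameter change (default
#'   1e-6; well below the profile resolution a 0.01 grid step needs).
#' @param em_max_iter EM iteration cap per grid point (default 5000).
#' @param n_boot bootstrap resamples for the standard error (default 200);
#'   `0` skips the bootstrap (`se = NA`).
#' @param boot_grid optional coarser/narrower grid for the bootstrap
#'   replicates; defaults to `theta_grid` restricted to within 0.5 of the
#'   point estimate (the bootstrap only needs the local spread of the
#'   argmax).
#' @param flat_tol objective range below which the profile is flagged flat
#'   (default 1e-3).
#' @return an [MREstimate] with method `"MRMix"`; the profile curve
#'   (`theta`, `objective`, `valid`) sits in the `profile` slot, the fitted
#'   `pi0` and `sigma2` at the argmax in their slots.
#' @export
mrMix <- function(pairs, theta_grid = seq(-2, 2, by = 0.01), em_tol = 1e-6,
                  em_max_iter = 5000L, n_boot = 200L, boot_grid = NULL,
                  flat_tol = 1e-3) {
  p <- if (is(pairs, "StandardizedPairs")) pairs@pairs else pairs
  if (nrow(p) < 10L)
    stop("mixture estimation needs at least 10 instruments")
  theta_grid <- sort(theta_grid)
  fit <- .mixProfile(p$gamma, p$se_gamma, p$Gamma, p$se_Gamma, theta_grid,
                     em_tol, em_max_iter)
  if (!any(fit$valid))
    stop("EM failed to converge at every grid point")
  if (any(!fit$valid))
    warning(sprintf("mrMix: EM did not converge at %d grid point(s); skipped",
                    sum(!fit$valid)))
  best <- .gridArgmax(theta_grid, fit$pi0, fit$valid)
  obj_range <- diff(range(fit$pi0[fit$valid]))
  unstable <- obj_range < flat_tol
  if (unstable)
    warning("mrMix: flat profile (objective range ", signif(obj_range, 3),
            "); estimate is unstable")

  se <- NA_real_
  if (n_boot > 0L) {
    bg <- if (is.null(boot_grid)) {
      keep <- abs(theta_grid - theta_grid[best]) <= 0.5
      if (sum(keep) < 10L) theta_grid else theta_grid[keep]
    } else sort(boot_grid)
    m <- nrow(p)
    boot_tol <- max(em_tol, 1e-5)  # only the argmax location is needed
    boot_theta <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(m, m, replace = TRUE)
      bf <- .mixProfile(p$gamma[idx], p$se_gamma[idx], p$Gamma[idx],
                        p$se_Gamma[idx], bg, boot_tol, em_max_iter)
      boot_theta[b] <- if (any(bf$valid))
        bg[.gridArgmax(bg, bf$pi0, bf$valid)] else NA_real_
    }
    se <- stats::sd(boot_theta, na.rm = TRUE)
  }
  profile <- data.frame(theta = theta_grid, objective = fit$pi0,
                        valid = fit$valid)
  .mrEstimate("MRMix", theta_grid[best], se, nrow(p),
              pi0 = fit$pi0[best], sigma2 = fit$sigma2[best],
              iterations = as.integer(max(fit$iters)),
              converged = all(fit$valid), profile = profile,
              unstable = unstable)
}

# argmax over valid grid points; ties broken toward smaller |theta|
.gridArgmax <- function(grid, obj, valid) {
  obj2 <- ifelse(valid, obj, -Inf)
  best <- which(obj2 == max(obj2))
  best[which.min(abs(grid[best]))]
}

# EM for the two-component scale mixture, vectorized across the theta grid.
# Returns per-grid-point pi0, sigma2, convergence flag and iteration count.
.mixProfile <- function(gamma, se_gamma, Gamma, se_Gamma, grid,
                        em_tol = 1e-6, em_max_iter = 5000L,
                        sigma2_floor = 1e-12) {
  m <- length(gamma); G <- length(grid)
  th <- matrix(grid, m, G, byrow = TRUE)
  d <- Gamma - th * gamma                       # m x G residuals
  s2 <- se_Gamma^2 + th^2 * se_gamma^2          # m x G null variances
  d2 <- d^2
  l0 <- -0.5 * (log(s2) + d2 / s2)              # null log-density: constant
  pi0 <- rep(0.9, G)
  sigma2 <- pmax(colMeans(d2 - s2), 100 * sigma2_floor)
  active <- rep(TRUE, G)
  iters <- integer(G)
  it <- 0L
  while (any(active) && it < em_max_iter) {
    it <- it + 1L
    a <- which(active)
    s2a <- s2[, a, drop = FALSE]; d2a <- d2[, a, drop = FALSE]
    v1 <- sweep(s2a, 2L, sigma2[a], `+`)
    l1 <- -0.5 * (log(v1) + d2a / v1)
    # responsibility of the pleiotropic component, computed in log space so
    # boundary pi0 and extreme density ratios stay finite
    pi0c <- pmin(pmax(pi0[a], 1e-12), 1 - 1e-12)
    lodds <- sweep(l0[, a, drop = FALSE] - l1, 2L, log(pi0c / (1 - pi0c)), `+`)
    r1 <- 1 / (1 + exp(pmin(lodds, 700)))       # responsibility: pleiotropic
    pi0_new <- 1 - colMeans(r1)
    # hierarchical M-step for sigma2: latent effect u ~ N(0, sigma2) with
    # E[u^2 | d] = sigma2*s2/v1 + (sigma2*d/v1)^2
    su <- sweep(1 / v1, 2L, sigma2[a], `*`)     # sigma2/v1
    eu2 <- su * s2a + (su * d[, a, drop = FALSE])^2
    num <- colSums(r1 * eu2)
    den <- colSums(r1)
    sigma2_new <- ifelse(den > 1e-12, pmax(num / den, sigma2_floor),
                         sigma2[a])
    # pi0 is the profile objective and carries the tight tolerance; sigma2
    # is a nuisance scale whose slow geometric decay toward the floor is
    # benign, so it gets a fixed looser relative criterion
    conv <- abs(pi0_new - pi0[a]) < em_tol &
      abs(sigma2_new - sigma2[a]) / (sigma2[a] + 1e-10) < 1e-4
    pi0[a] <- pi0_new
    sigma2[a] <- sigma2_new
    iters[a] <- it
    active[a] <- !conv
  }
  list(pi0 = pmin(pmax(pi0, 0), 1), sigma2 = sigma2,
       valid = !active, iters = iters)
}
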