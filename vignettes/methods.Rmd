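---
title: "Methods: two-sample MR with pleiotropy handling in pleioMR"
author: "pleioMR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with pleiotropy handling in pleioMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioMR)
```

# The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables. For variant $i$, let $\gamma_i$ be its standardized effect on the
exposure and $\Gamma_i$ its standardized effect on the outcome. Under the
instrumental-variable assumptions the two are proportional,
$\Gamma_i = \theta\,\gamma_i$, and $\theta$ is the causal effect of one
standard deviation of exposure on the outcome's log-odds. Horizontal
pleiotropy breaks the proportionality: an invalid instrument carries a
direct effect $\alpha_i$, so that $\Gamma_i = \theta\gamma_i + \alpha_i$.
Every estimator in this package is a different answer to the question
"what do we do about the $\alpha_i$?".

Observed per-allele GWAS coefficients are first put on a common unitless
scale. The exposure effect is divided by its standard error times
$\sqrt{n_E}$ (so the standardized effect is the z-score scaled by
$n_E^{-1/2}$, with $se_{\hat\gamma} = n_E^{-1/2}$ exactly), and the outcome
effect is multiplied by the allele-frequency standard deviation
$\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})}$, with its standard error scaled by
the same factor. Both transforms preserve each variant's z-score exactly,
which the test suite asserts as an identity. The two transforms are
deliberately asymmetric — the exposure is rescaled through its z-score, the
outcome through the genotype variance — and are implemented exactly in this
form; their inverses (`backTransform`) are used by the synthetic generator
so the standardization code path is exercised end to end. Note that the
exposure inverse is underdetermined (the per-allele standard error divides
out); the generator fills it with the standard GWAS approximation
$se_\beta = 1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n}$, and an explicit
`se_beta` override exists.

# The estimators

**Wald ratio.** $\hat\theta_i = \hat\Gamma_i/\hat\gamma_i$ with the
first-order delta-method standard error. Undefined at $\hat\gamma_i = 0$.

**IVW.** Weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through the
origin with fixed-effect weights $1/se_{\hat\Gamma}^2$. This is the
maximum-precision combination of the per-variant ratios but attributes all
of $\hat\Gamma$ to the causal path, so directional pleiotropy with mean $c$
biases it by approximately $c\,E[\gamma]/E[\gamma^2]$ (the acceptance suite
checks this analytic bias on simulated data). The weighting order is
configurable: `weighting = "random"` inflates the standard error by
$\max(1, \sqrt{Q/(m-1)})$ (multiplicative random effects); the fixed-effect
form is the default because the package's own pruning estimator is the
intended answer to overdispersion.

**MR-Egger.** The same regression with a free intercept. Under the InSIDE
assumption (instrument strength independent of direct effects) the slope
consistently estimates $\theta$ and the intercept estimates the mean
directional pleiotropy; the intercept's two-sided normal test is the
standard pleiotropy diagnostic. Instruments are oriented so
$\hat\gamma_i \ge 0$ before fitting (the conventional Egger orientation,
without which the intercept is not identified); `orient = FALSE` disables
this.

**Iterative pleiotropy pruning (IMRP-style).** Alternates (i) estimating
$\theta$ on the retained instruments, (ii) testing every instrument's
residual $\hat\Gamma_i - \theta\hat\gamma_i$ against its null standard
deviation
$\sqrt{se_{\hat\Gamma}^2 + \theta^2 se_{\hat\gamma}^2 -
2\theta\rho\,se_{\hat\Gamma} se_{\hat\gamma}}$, and (iii) excluding
instruments with p below `alpha_pleio`, until the excluded set reaches a
fixed point. $\rho$ is the correlation between the exposure and outcome
estimate errors induced by shared participants (`rho_overlap`, default 0;
exposed because overlapping biobank samples are common). The same
overlap-corrected variance supplies the weights of the final estimate.
Defaults: `alpha_pleio = 0.05` (the nominal per-variant evidence level,
with a Bonferroni 0.05/m flag also reported for plotting), `max_iter = 50`,
initialization at the all-instrument IVW estimate. `alpha_pleio = 0`
short-circuits to IVW exactly. Note the per-variant test holds its nominal
size only at the true $\theta$; at the estimated $\theta$ the empirical
size is very slightly conservative, which the type-I-error test measures
at the truth for that reason.

**Normal-mixture profile.** For each candidate $\theta$ on a grid, the
residuals $d_i = \hat\Gamma_i - \theta\hat\gamma_i$ have known null
variance $s_i^2 = se_{\hat\Gamma}^2 + \theta^2 se_{\hat\gamma}^2$, and a
two-component mixture $\pi_0 N(0, s_i^2) + (1-\pi_0) N(0, s_i^2+\sigma^2)$
is fitted by EM. At the true $\theta$ the valid majority's residuals are
pure sampling noise, so the fitted null proportion $\pi_0$ peaks there;
the estimate is the grid argmax of $\pi_0$ and the profile curve is
returned for diagnostics. A sharp peak signals stable estimation; a flat
profile (objective range below `flat_tol = 1e-3`) is flagged `unstable`
and corresponds to the wide-confidence-interval regime seen when outcome
GWAS are small.

# Numerical choices

- **EM details.** The $\sigma^2$ update uses the closed-form hierarchical
  M-step (latent direct effect $u_i \sim N(0,\sigma^2)$ with conditional
  moments $\sigma^2 s_i^2/(\sigma^2+s_i^2)$ and $\sigma^2 d_i/(\sigma^2+s_i^2)$),
  vectorized across the whole grid as matrix operations. Responsibilities
  are computed in log space so boundary values of $\pi_0$ and extreme
  density ratios stay finite. $\sigma^2$ is floored at $10^{-12}$ to
  prevent component collapse; $\pi_0$ starts at 0.9. Convergence requires
  the $\pi_0$ change below `em_tol` ($10^{-6}$, far below the resolution a
  0.01 grid step needs) and the $\sigma^2$ relative change below $10^{-4}$
  ($\sigma^2$ is a nuisance whose slow geometric decay toward the floor on
  the degenerate likelihood ridge is benign). When the two components
  nearly coincide, $(\pi_0, \sigma^2)$ lie on a likelihood ridge and the
  fitted $\pi_0$ is weakly identified even though the argmax over $\theta$
  is stable — tests therefore assert the argmax, not the exact $\pi_0$.
- **Bootstrap.** The standard error is a nonparametric bootstrap over
  instruments (default 200 resamples). Bootstrap replicates profile a grid
  restricted to within 0.5 of the point estimate: the bootstrap only needs
  the local spread of the argmax, and this keeps the cost linear in what
  matters. Replicates use a slightly looser EM tolerance ($10^{-5}$) for
  the same reason.
- **Ties and determinism.** Grid-argmax ties break toward the smaller
  $|\theta|$ (the more conservative effect). Clumping ties on equal
  p-values break lexicographically by variant id so output is
  bit-reproducible across platforms and input orderings. All simulation
  entry points take an integer seed and are deterministic given it.
- **Confidence intervals.** Odds ratios are $e^{\hat\theta}$ with
  $e^{\hat\theta \pm 1.959964\,se}$ limits.

# Data handling decisions

- **Frequency filter.** "Allele frequency above a threshold" is read as a
  minor-allele-frequency criterion, $\min(\mathrm{eaf}, 1-\mathrm{eaf}) >$
  threshold; typical thresholds are $10^{-4}$ (0.01%) for a single-ancestry
  analysis and $10^{-3}$ (0.1%) for multi-ethnic data. Records with missing
  frequency pass only a zero threshold, because the outcome standardization
  needs the MAF downstream.
- **Meta-analysis.** Fixed-effect inverse-variance only, with cohorts
  aligned to the first cohort's effect allele (swap and strand-complement
  reconciliation; irreconcilable records excluded and counted). Cochran's
  $Q$ on $k-1$ degrees of freedom is tested at a Bonferroni-adjusted
  threshold over the variants present in at least two cohorts; flagged
  variants are *retained but reported*, which makes the screen an audit
  rather than a filter.
- **Harmonization.** Alleles are matched directly, as a swap (sign flip,
  frequency mirrored), or after strand complement. Palindromic variants
  (A/T, C/G) cannot be resolved by labels; the default `infer` policy uses
  allele frequencies when both MAFs are below 0.4 and drops the variant
  otherwise, which is the conservative standard practice; `drop` and
  `keep` policies are available because published analyses differ.
- **Clumping.** Greedy index selection sorted by ascending p-value,
  removing neighbours within the physical window whose $r^2$ meets the
  threshold. The "LD coefficient" is interpreted as $r^2$ (the PLINK
  `--clump-r2` semantics), not $|r|$. Pairs absent from the supplied LD
  reference count as independent with a logged warning, matching PLINK's
  behaviour with incomplete panels. The secondary threshold `clump_p2` is
  accepted for config compatibility; with `p2 = p1` (the default) it does
  not alter the selection.
- **Missing per-variant sample sizes.** The exposure sample size enters the
  standardization directly, so records without `n` are invalid and are
  dropped at read time; this requirement is deliberate and documented
  rather than imputed around.

# The synthetic generator

`simulateMRData` draws true standardized instrument effects
$\gamma_i \sim N(0, \sigma_\gamma^2)$ with $\sigma_\gamma = 0.01$ by
default — the scale of genome-wide-significant standardized effects in
biobank-sized GWAS, matching effect-size standard deviations around
0.009–0.010 seen for cardiometabolic traits. A configurable fraction of
instruments receives direct effects $\alpha_i$, mean-zero (`balanced`) or
mean-shifted (`directional`). Per-cohort observed effects add
$1/\sqrt{n}$-scaled Gaussian noise, correlated `rho_overlap` between the
exposure and outcome draws of the same cohort to emulate shared
participants. Default cohort sizes ($n$ = 650{,}000 exposure, 10{,}000
outcome) mirror the asymmetry of a huge exposure GWAS paired with a modest
outcome GWAS. Effects are generated on the standardized scale and
back-transformed to per-allele coefficients so the pipeline's own
standardization is what recovers them. Optional LD blocks (constant
within-block $r^2$, blocks within one clumping window, independent across
blocks) support clumping tests, and an `inject_allele_noise` switch plants
swapped-allele and palindromic records to exercise harmonization.

What the generator does *not* emulate: realistic genome-wide LD structure,
ancestry admixture, winner's-curse selection of instruments, non-normal
effect-size distributions, and case-control ascertainment effects on the
outcome scale. Passing tests therefore demonstrate the correctness of the
estimators under their stated statistical model, not robustness to every
failure mode of real GWAS data.

# Problem sizes and test design

The test suite checks closed-form examples exactly, equates IVW/Egger with
independent least-squares oracles to $10^{-10}$ over 100 random instances,
and equates greedy clumping with a brute-force transcription of the
procedure over 200 random instances of up to 20 variants. Monte-Carlo
checks use sizes chosen to make their tolerances meaningful on one CPU:
10{,}000 variants for the pleiotropy-test size (tolerance
$3\sqrt{0.05\cdot 0.95/10^4}$), 5{,}000 variants for the null $Q$
calibration, 200 replicates for the Egger directional-pleiotropy coverage,
and 50 replicates of $m = 200$ instruments (40% invalid, 30 bootstrap
resamples each) for the mixture estimator, asserting the argmax within
three bootstrap standard errors of the truth in at least 95% of
replicates.

# Known limitations

- The mixture estimator's $\pi_0$ is reported as fitted but is weakly
  identified when pleiotropy variance is small relative to sampling noise;
  use the profile curve and the `unstable` flag before interpreting it.
- The power calculation is an analytic approximation (normal
  noncentrality with variance $n\,r^2\,\phi(1-\phi)$ for case fraction
  $\phi$); it ignores weak-instrument bias and pleiotropy, and
  simulation-based power via the generator is the recommended complement.
- The pruning estimator's exclusion rule tests at the *estimated* effect;
  with very few instruments or pervasive pleiotropy the iteration can
  converge to a biased fixed point — the all-excluded and non-convergence
  conditions are surfaced as errors/flags rather than silently handled.
- Liability-scale conversion for binary exposures, multivariable MR,
  weighted-median/mode estimators and proxy-variant lookup are out of
  scope.
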