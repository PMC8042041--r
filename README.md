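# pleioMR

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
explicit handling of horizontal pleiotropy.

MR uses genetic variants as instrumental variables to estimate the causal
effect of an exposure (e.g. type II diabetes, blood pressure, BMI) on a
binary outcome (e.g. hospitalization with a disease) from two independent
GWAS. Each instrument *i* contributes a Wald ratio
θ̂ᵢ = Γ̂ᵢ / γ̂ᵢ, where γ̂ᵢ and Γ̂ᵢ are the variant's standardized effects
on the exposure and the outcome:

    γ̂ᵢ  = β̂_E,i / (se_E,i · √n_E,i)          se_γ̂ᵢ = n_E,i^(−1/2)
    Γ̂ᵢ  = β̂_Y,i · √(2·MAFᵢ·(1 − MAFᵢ))        se_Γ̂ᵢ = se_Y,i · √(2·MAFᵢ·(1 − MAFᵢ))

The package implements the full workflow around these quantities:

- **sumstats I/O** — configurable delimited-text ingestion with validation
  and minor-allele-frequency filtering (`readSumstats`, `filterByFrequency`,
  `writeSumstats`);
- **meta-analysis** — fixed-effect inverse-variance combination of per-cohort
  GWAS with Cochran-Q heterogeneity screening at a Bonferroni-adjusted
  threshold (`metaAnalyze`);
- **harmonization** — alignment of outcome records to the exposure effect
  allele, including strand flips and a configurable palindromic-variant
  policy (`harmonizeSumstats`);
- **LD clumping** — greedy PLINK-style selection of independent genome-wide
  significant instruments (p < 5·10⁻⁸, r² < 0.1, 500 kb window by default;
  `clumpVariants`);
- **estimators** — Wald ratio, inverse-variance weighted (IVW), MR-Egger
  regression (slope + pleiotropy-intercept test), iterative pleiotropy
  pruning with sample-overlap correction (`mrIMRP`), and a normal-mixture
  profile estimator (`mrMix`) whose objective is the fitted proportion of
  valid instruments;
- **power** — a closed-form two-sided normal approximation for the IVW test
  on a binary outcome (`mrPower`);
- **synthetic data** — a multi-cohort summary-statistic generator with known
  causal effect, planted pleiotropy (balanced or directional), LD blocks and
  optional exposure–outcome sample overlap (`simulateMRData`), so the whole
  chain is testable without any external download;
- **pipeline** — a one-call orchestration from a YAML config to a report
  bundle of TSVs and a run manifest (`runPipeline`), plus a thin CLI at
  `scripts/mr_pipeline.R` (subcommands `run`, `simulate`, `power`).

## Worked example

Simulate a two-cohort study with a true causal effect θ = 0.3 and 10%
directionally pleiotropic instruments, then run the analysis chain:

```r
library(pleioMR)

sim <- simulateMRData(simConfig(m = 150, theta_true = 0.3, k_cohorts = 2,
                                pleio_fraction = 0.1,
                                pleio_mode = "directional", seed = 42))
me  <- metaAnalyze(sim$exposure)          # combine exposure cohorts
mo  <- metaAnalyze(sim$outcome)           # combine outcome cohorts
h   <- harmonizeSumstats(me@table, mo@table)
sel <- clumpVariants(h, sim$ld)           # 105 independent instruments
hs  <- new("HarmonizedPairs",
           pairs = records(h)[records(h)$snp %in% sel, ], log = integer())
std <- standardizePairs(hs)

mrIVW(std)
#> MREstimate [IVW]
#>   theta = 0.2048 (se 0.0539), p = 0.000145
#>   OR = 1.227 (95% CI 1.104-1.364), 105 instruments

mrIMRP(std)
#> MREstimate [IMRP]
#>   theta = 0.2549 (se 0.0561), p = 5.58e-06
#>   OR = 1.290 (95% CI 1.156-1.440), 94 instruments
#>   11 excluded in 3 iteration(s)
```

IVW, which cannot distinguish pleiotropic from valid instruments, is pulled
away from the truth by the directional pleiotropy; the iterative pruning
estimator excludes 11 flagged variants and moves back toward θ = 0.3. The
Egger fit (`mrEgger(std)`) reports slope 0.130 with intercept p = 0.554, and
the mixture profile (`mrMix(std)`) peaks at θ = 0.23 (bootstrap se 0.087).
The analytic power of an IVW test for an odds ratio of e^0.3 ≈ 1.35 with
instruments explaining 2% of exposure variance in an outcome GWAS of
10,908 (22.5% cases) is:

```r
mrPower(0.3, r2_instrument = 0.02, n_outcome = 10908,
        case_fraction = 2430 / 10808)$power
#> [1] 0.4562295
```

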