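Package: pleioMR
Title: Two-Sample Mendelian Randomization with Horizontal-Pleiotropy Handling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: reading, validating and frequency-filtering summary-statistic
    tables; fixed-effect inverse-variance meta-analysis across cohorts with
    Cochran heterogeneity screening; allele harmonization between exposure and
    outcome studies; greedy LD clumping of genome-wide-significant instruments;
    standardization of per-allele effects to a unitless scale; causal-effect
    estimation by the Wald ratio, inverse-variance weighting, MR-Egger
    regression, iterative pleiotropy pruning with sample-overlap correction,
    and a normal-mixture profile estimator; an analytic power approximation
    for binary outcomes; and a synthetic multi-cohort summary-statistic
    generator with known causal structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
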