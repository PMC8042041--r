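#!/usr/bin/env Rscript
# Thin command-line wrapper over the pleioMR package.
#
#   Rscript scripts/mr_pipeline.R run --config analysis.yaml
#   Rscript scripts/mr_pipeline.R simulate --m 200 --theta 0.3 \
#       --pleio-fraction 0.1 --out-dir sim/ [--seed 1]
#   Rscript scripts/mr_pipeline.R power --theta 0.26 --r2 0.02 \
#       --n-outcome 10908 --case-fraction 0.22 [--alpha 0.05]

suppressMessages({
  library(optparse)
  library(pleioMR)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: mr_pipeline.R <run|simulate|power> [options]", call. = FALSE)
cmd <- args[[1L]]
rest <- args[-1L]

if (cmd == "run") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"))), args = rest)
  if (is.null(o$config)) stop("run needs --config <yaml>", call. = FALSE)
  res <- runPipeline(o$config)
  print(res$estimates, row.names = FALSE)
} else if (cmd == "simulate") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--m", type = "integer", default = 100L),
    make_option("--theta", type = "double", default = 0.2),
    make_option("--k-cohorts", type = "integer", default = 1L,
                dest = "k_cohorts"),
    make_option("--pleio-fraction", type = "double", default = 0,
                dest = "pleio_fraction"),
    make_option("--pleio-mode", type = "character", default = "balanced",
                dest = "pleio_mode"),
    make_option("--rho-overlap", type = "double", default = 0,
                dest = "rho_overlap"),
    make_option("--out-dir", type = "character", default = "sim",
                dest = "out_dir"),
    make_option("--seed", type = "integer", default = 1L))), args = rest)
  sim <- simulateMRData(simConfig(
    m = o$m, theta_true = o$theta, k_cohorts = o$k_cohorts,
    pleio_fraction = o$pleio_fraction, pleio_mode = o$pleio_mode,
    rho_overlap = o$rho_overlap, seed = o$seed))
  dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sim$exposure))
    writeSumstats(sim$exposure[[i]],
                  file.path(o$out_dir, sprintf("exposure_%d.tsv", i)))
  for (i in seq_along(sim$outcome))
    writeSumstats(sim$outcome[[i]],
                  file.path(o$out_dir, sprintf("outcome_%d.tsv", i)))
  writeSimTruth(sim, o$out_dir)
  cat("wrote", 2L * length(sim$exposure) + 2L, "files to", o$out_dir, "\n")
} else if (cmd == "power") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--theta", type = "double"),
    make_option("--r2", type = "double"),
    make_option("--n-outcome", type = "integer", dest = "n_outcome"),
    make_option("--case-fraction", type = "double", dest = "case_fraction"),
    make_option("--alpha", type = "double", default = 0.05))), args = rest)
  res <- mrPower(o$theta, o$r2, o$n_outcome, o$case_fraction, o$alpha)
  write.table(res, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
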