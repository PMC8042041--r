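#' Read a pipeline run configuration
#'
#' Parses a YAML file with a flat key set mirroring the analysis
#' parameters. Recognized keys (defaults in parentheses): `exposure_files`
#' (list, required), `outcome_files` (list, required), `ld_matrix` or
#' `ld_pairs` (optional path), `clump_kb` (500), `clump_p1` (5e-8),
#' `clump_p2` (5e-8), `clump_r2` (0.1), `min_freq` (1e-4), `het_alpha`
#' (0.05), `alpha_pleio` (0.05), `rho_overlap` (0), `palindromic`
#' ("infer"), `estimators` (IVW, Egger, IMRP, MRMix), `mrmix_grid_from`
#' (-2), `mrmix_grid_to` (2), `mrmix_grid_step` (0.01), `mrmix_boot`
#' (200), `out_dir` (required), `seed` (1), plus optional `column_map` and
#' `delimiter` for non-canonical input dialects.
#'
#' @param path YAML file path.
#' @return a validated named list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(clump_kb = 500, clump_p1 = 5e-8, clump_p2 = 5e-8,
                   clump_r2 = 0.1, min_freq = 1e-4, het_alpha = 0.05,
                   alpha_pleio = 0.05, rho_overlap = 0,
                   palindromic = "infer",
                   estimators = c("IVW", "Egger", "IMRP", "MRMix"),
                   mrmix_grid_from = -2, mrmix_grid_to = 2,
                   mrmix_grid_step = 0.01, mrmix_boot = 200,
                   delimiter = "\t", column_map = character(), seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("exposure_files", "outcome_files", "out_dir"))
    if (is.null(cfg[[k]])) stop("run config missing required key: ", k)
  paths <- c(unlist(cfg$exposure_files), unlist(cfg$outcome_files),
             cfg$ld_matrix, cfg$ld_pairs)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("referenced input file(s) not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "RunConfig")
}

#' Run the end-to-end two-sample MR analysis
#'
#' Executes read, frequency filter, per-trait meta-analysis, harmonization,
#' LD clumping, standardization, and every requested estimator, writing
#' per-stage TSVs, a text log and a JSON run manifest into `out_dir`.
#' Outputs: `meta_exposure.tsv` / `meta_outcome.tsv` (combined tables),
#' `heterogeneity.tsv`, `harmonization_log.tsv` (drop counts by reason),
#' `instruments.tsv` (selected ids), `standardized_pairs.tsv`,
#' `effect_summary.tsv` (correlation and effect-size summary block),
#' `estimates.tsv` (one row per estimator with OR and 95% CI),
#' `pleiotropy.tsv` (per-variant flags, when IMRP runs),
#' `mrmix_profile.tsv` (theta vs objective, when MRMix runs),
#' `run_log.txt` and `manifest.json`. Re-running with an identical config
#' and inputs reproduces identical outputs.
#'
#' @param config a `"RunConfig"` list from [readRunConfig()], or a path to
#'   a YAML config file.
#' @return named list with the estimates table, the per-stage objects and
#'   the output paths, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cf$out_dir, "run_log.txt")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logline <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...)), logcon)
  }
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  set.seed(cf$seed)
  drops <- list()
  note_drops <- function(stage_name, log) {
    if (length(log) && sum(log)) {
      drops[[length(drops) + 1L]] <<- data.frame(
        stage = stage_name, reason = names(log), count = as.integer(log))
      for (r in names(log)[log > 0])
        logline("  drop [%s] %s: %d", stage_name, r, log[[r]])
    }
  }

  read_side <- function(paths, label) {
    lapply(seq_along(paths), function(i) {
      tb <- readSumstats(paths[[i]], column_map = cf$column_map,
                         delimiter = cf$delimiter,
                         trait_name = label)
      note_drops(sprintf("read_%s_%d", label, i), attr(tb, "drop_log"))
      tb <- filterByFrequency(tb, cf$min_freq)
      note_drops(sprintf("freq_%s_%d", label, i), attr(tb, "drop_log"))
      tb
    })
  }

  expo_tabs <- stage("read_exposure",
                     read_side(unlist(cf$exposure_files), "exposure"))
  outc_tabs <- stage("read_outcome",
                     read_side(unlist(cf$outcome_files), "outcome"))

  meta_of <- function(tabs, label) {
    ma <- metaAnalyze(tabs, het_alpha = cf$het_alpha)
    note_drops(sprintf("meta_%s", label), attr(ma@table, "drop_log"))
    logline("meta %s: %d variants, %d heterogeneity-flagged", label,
            nrow(ma@perVariant), sum(ma@perVariant$het_flag))
    ma
  }
  meta_e <- stage("meta_exposure", meta_of(expo_tabs, "exposure"))
  meta_o <- stage("meta_outcome", meta_of(outc_tabs, "outcome"))
  writeSumstats(meta_e@table, file.path(cf$out_dir, "meta_exposure.tsv"))
  writeSumstats(meta_o@table, file.path(cf$out_dir, "meta_outcome.tsv"))
  het <- rbind(cbind(trait = "exposure", meta_e@perVariant),
               cbind(trait = "outcome", meta_o@perVariant))
  utils::write.table(het, file.path(cf$out_dir, "heterogeneity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  harm <- stage("harmonize", {
    h <- harmonizeSumstats(meta_e@table, meta_o@table,
                           palindromic = cf$palindromic)
    note_drops("harmonize", h@log)
    logline("harmonize: %d variants retained", nVariants(h))
    h
  })

  ld <- stage("ld", {
    if (!is.null(cf$ld_matrix)) readLDMatrix(cf$ld_matrix)
    else if (!is.null(cf$ld_pairs)) readLDPairs(cf$ld_pairs)
    else ldInfo(character(), matrix(numeric(), 0, 0))
  })

  instruments <- stage("clump", {
    sel <- clumpVariants(harm, ld, p1 = cf$clump_p1, r2_max = cf$clump_r2,
                         window_kb = cf$clump_kb)
    logline("clump: %d index variants selected of %d candidates",
            length(sel), sum(harm@pairs$p_exp < cf$clump_p1))
    n_clumped <- sum(harm@pairs$p_exp < cf$clump_p1) - length(sel)
    note_drops("clump", c(clumped_away = n_clumped))
    sel
  })
  writeLines(instruments, file.path(cf$out_dir, "instruments.tsv"))
  if (length(instruments) < 3L)
    stop("pipeline stage 'clump' failed: fewer than 3 instruments selected")
  harm_sel <- new("HarmonizedPairs",
                  pairs = harm@pairs[harm@pairs$snp %in% instruments, ,
                                     drop = FALSE],
                  log = harm@log)

  std <- stage("standardize", {
    s <- standardizePairs(harm_sel)
    note_drops("standardize", attr(s, "drop_log"))
    s
  })
  writeStandardizedPairs(std, file.path(cf$out_dir, "standardized_pairs.tsv"))

  ec <- stage("effect_summary", effectCorrelation(std))
  summ <- cbind(effect = rownames(ec@summary), ec@summary,
                rho = ec@rho, se_rho = ec@seRho, m = ec@m)
  utils::write.table(summ, file.path(cf$out_dir, "effect_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ests <- list()
  for (method in cf$estimators) {
    ests[[method]] <- stage(paste0("estimate_", method), switch(
      method,
      IVW = mrIVW(std),
      Egger = mrEgger(std),
      IMRP = mrIMRP(std, alpha_pleio = cf$alpha_pleio,
                    rho_overlap = cf$rho_overlap),
      MRMix = mrMix(std,
                    theta_grid = seq(cf$mrmix_grid_from, cf$mrmix_grid_to,
                                     by = cf$mrmix_grid_step),
                    n_boot = cf$mrmix_boot),
      stop("unknown estimator: ", method)))
  }
  est_df <- do.call(rbind, lapply(ests, function(e) data.frame(
    method = e@method, theta = e@theta, se = e@se, pvalue = e@pvalue,
    odds_ratio = e@oddsRatio, ci_low = e@ciLow, ci_high = e@ciHigh,
    n_snps = e@nSNPs, n_excluded = length(e@excluded),
    intercept = e@intercept, intercept_p = e@interceptP,
    stringsAsFactors = FALSE)))
  utils::write.table(est_df, file.path(cf$out_dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(ests$IMRP))
    utils::write.table(ests$IMRP@pleiotropy,
                       file.path(cf$out_dir, "pleiotropy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ests$MRMix))
    utils::write.table(ests$MRMix@profile[, c("theta", "objective")],
                       file.path(cf$out_dir, "mrmix_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  drop_df <- if (length(drops)) do.call(rbind, drops)
             else data.frame(stage = character(), reason = character(),
                             count = integer())
  utils::write.table(drop_df, file.path(cf$out_dir, "harmonization_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg_plain <- unclass(cf)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    config = cfg_plain,
    config_md5 = as.character(tools::md5sum(
      local({ tf <- tempfile(); writeLines(cfg_json, tf); tf }))),
    seed = cf$seed,
    n_instruments = length(instruments),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("pleioMR")))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  logline("pipeline complete: %d estimator(s)", length(ests))
  invisible(list(estimates = est_df, estimate_objects = ests,
                 instruments = instruments, standardized = std,
                 harmonized = harm, meta_exposure = meta_e,
                 meta_outcome = meta_o, effect_correlation = ec,
                 out_dir = cf$out_dir))
}
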