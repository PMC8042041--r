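#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (optionally gzip-compressed) of per-variant
#' association records into a validated [SumStats] object. Source column
#' names are mapped onto the canonical schema
#' `snp, chr, pos, ea, oa, eaf, beta, se, p, n` through `column_map`.
#' Rows violating record invariants (non-positive se, eaf outside \[0, 1\],
#' p outside (0, 1\], n below 1, identical alleles, duplicated id,
#' unparseable numerics) are dropped; the per-reason counts are attached as
#' the `"drop_log"` attribute and reported via a message. Alleles are
#' upper-cased on read. Row order is preserved.
#'
#' @param path file path; `.gz` files are decompressed transparently.
#' @param column_map named character vector mapping canonical names to
#'   source header names, e.g. `c(beta = "Effect")`. Unmapped canonical
#'   names are looked up verbatim.
#' @param delimiter single field-separator character (default tab).
#' @param trait_name,trait_type,ancestry metadata carried on the result.
#'
#' @return a [SumStats] object with attribute `"drop_log"` (named integer).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tp\tn",
#'              "rs1\t1\t100\tA\tG\t0.2\t0.05\t0.01\t1e-8\t10000"), tf)
#' ss <- readSumstats(tf)
#' nVariants(ss)
#' @export
readSumstats <- function(path, column_map = character(), delimiter = "\t",
                         trait_name = NA_character_,
                         trait_type = c("quantitative", "binary"),
                         ancestry = NA_character_) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path))
    stop("summary-statistic file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- utils::read.table(con, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  # resolve the source column for each canonical name
  src <- stats::setNames(.SUMSTAT_COLS, .SUMSTAT_COLS)
  if (length(column_map)) {
    bad <- setdiff(names(column_map), .SUMSTAT_COLS)
    if (length(bad))
      stop("column_map keys must be canonical names; unknown: ",
           paste(bad, collapse = ", "))
    src[names(column_map)] <- column_map
  }
  missing_cols <- src[!src %in% names(raw)]
  if (length(missing_cols))
    stop("mandatory column(s) missing from header: ",
         paste(sprintf("%s (source '%s')", names(missing_cols), missing_cols),
               collapse = ", "))
  rec <- data.frame(
    snp = raw[[src["snp"]]],
    chr = raw[[src["chr"]]],
    pos = suppressWarnings(as.integer(raw[[src["pos"]]])),
    ea  = toupper(raw[[src["ea"]]]),
    oa  = toupper(raw[[src["oa"]]]),
    eaf = suppressWarnings(as.numeric(raw[[src["eaf"]]])),
    beta = suppressWarnings(as.numeric(raw[[src["beta"]]])),
    se  = suppressWarnings(as.numeric(raw[[src["se"]]])),
    p   = suppressWarnings(as.numeric(raw[[src["p"]]])),
    n   = suppressWarnings(as.numeric(raw[[src["n"]]])),
    stringsAsFactors = FALSE
  )
  if (nrow(rec) && mean(is.na(rec$beta) | is.na(rec$se)) > 0.5)
    stop("unparseable numeric fields in more than 50% of rows; ",
         "check delimiter and column_map")
  drop <- c(
    bad_numeric  = sum(is.na(rec$beta) | is.na(rec$se) | is.na(rec$p) |
                       is.na(rec$n) | is.na(rec$pos)),
    se_nonpos    = 0L, eaf_range = 0L, p_range = 0L, n_range = 0L,
    same_alleles = 0L, dup_snp = 0L
  )
  ok <- !(is.na(rec$beta) | is.na(rec$se) | is.na(rec$p) | is.na(rec$n) |
          is.na(rec$pos))
  bad <- ok & rec$se <= 0
  drop["se_nonpos"] <- sum(bad); ok <- ok & !bad
  bad <- ok & !is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)
  drop["eaf_range"] <- sum(bad); ok <- ok & !bad
  bad <- ok & (rec$p <= 0 | rec$p > 1)
  drop["p_range"] <- sum(bad); ok <- ok & !bad
  bad <- ok & rec$n < 1
  drop["n_range"] <- sum(bad); ok <- ok & !bad
  bad <- ok & rec$ea == rec$oa
  drop["same_alleles"] <- sum(bad); ok <- ok & !bad
  bad <- ok & duplicated(rec$snp)
  drop["dup_snp"] <- sum(bad); ok <- ok & !bad
  rec <- rec[ok, , drop = FALSE]
  rownames(rec) <- NULL
  if (sum(drop))
    message(sprintf("readSumstats: dropped %d invalid row(s) [%s]", sum(drop),
                    paste(sprintf("%s=%d", names(drop)[drop > 0],
                                  drop[drop > 0]), collapse = ", ")))
  out <- new("SumStats", records = rec, traitName = trait_name,
             traitType = trait_type, ancestry = ancestry)
  attr(out, "drop_log") <- drop
  out
}

#' Write a summary-statistic table in the canonical dialect
#'
#' Writes tab-delimited text with the canonical header; numeric fields are
#' serialized at full precision (17 significant digits) so that
#' `readSumstats(writeSumstats(x))` reproduces `x` exactly.
#'
#' @param table a [SumStats] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(table, path) {
  stopifnot(is(table, "SumStats"))
  rec <- table@records
  if (nrow(rec) == 0L) {
    writeLines(paste(.SUMSTAT_COLS, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- rec[, .SUMSTAT_COLS]
  for (col in c("eaf", "beta", "se", "p", "n"))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Filter variants by minor allele frequency
#'
#' Retains records with `min(eaf, 1 - eaf) > min_freq`, the standard
#' minor-allele reading of an allele-frequency inclusion threshold. Records
#' with missing eaf pass only when `min_freq = 0`; otherwise they are
#' dropped with a logged count because the standardization step needs the
#' frequency downstream. Record order is preserved; the filter is idempotent
#' and monotone in `min_freq`.
#'
#' @param table a [SumStats] object.
#' @param min_freq threshold in \[0, 0.5\]; e.g. `1e-4` (frequency above
#'   0.01%) or `1e-3` (above 0.1%).
#' @return a filtered [SumStats] with attribute `"drop_log"`.
#' @export
filterByFrequency <- function(table, min_freq) {
  stopifnot(is(table, "SumStats"),
            is.numeric(min_freq), length(min_freq) == 1L,
            min_freq >= 0, min_freq <= 0.5)
  rec <- table@records
  if (nrow(rec) == 0L || min_freq == 0) {
    attr(table, "drop_log") <- c(low_maf = 0L, missing_eaf = 0L)
    return(table)
  }
  missing_eaf <- is.na(rec$eaf)
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  keep <- !missing_eaf & maf > min_freq
  drop <- c(low_maf = sum(!keep & !missing_eaf), missing_eaf = sum(missing_eaf))
  if (drop["missing_eaf"])
    message(sprintf("filterByFrequency: dropped %d record(s) with missing eaf",
                    drop[["missing_eaf"]]))
  out <- new("SumStats",
             records = `rownames<-`(rec[keep, , drop = FALSE], NULL),
             traitName = table@traitName, traitType = table@traitType,
             ancestry = table@ancestry)
  attr(out, "drop_log") <- drop
  out
}

# internal constructor from a ready-made canonical data.frame
.sumstats <- function(rec, trait_name = NA_character_,
                      trait_type = "quantitative",
                      ancestry = NA_character_) {
  rownames(rec) <- NULL
  new("SumStats", records = rec, traitName = trait_name,
      traitType = trait_type, ancestry = ancestry)
}
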