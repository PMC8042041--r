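#' Read a square LD matrix
#'
#' Parses a tab-delimited square matrix of squared correlations with variant
#' ids as header and first column, into an [LDInfo] lookup.
#'
#' @param path TSV path; first column holds row labels.
#' @return an [LDInfo].
#' @export
readLDMatrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1L, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column labels differ")
  ldInfo(rownames(m), m)
}

#' Read a pairwise long-format LD table
#'
#' Parses a PLINK `.ld`-style long table with columns `SNP_A`, `SNP_B`, `R2`
#' (case-insensitive) into an [LDInfo]; unlisted pairs are independent.
#'
#' @param path delimited text path (whitespace- or tab-separated).
#' @return an [LDInfo].
#' @export
readLDPairs <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(raw)))
    stop("pairwise LD table needs columns SNP_A, SNP_B, R2")
  snps <- sort(unique(c(raw$SNP_A, raw$SNP_B)))
  m <- diag(1, length(snps))
  dimnames(m) <- list(snps, snps)
  ia <- match(raw$SNP_A, snps); ib <- match(raw$SNP_B, snps)
  m[cbind(ia, ib)] <- raw$R2
  m[cbind(ib, ia)] <- raw$R2
  ldInfo(snps, m)
}

#' Construct an LDInfo from an r-squared matrix
#'
#' @param snps character ids, matching the matrix order.
#' @param r2 square symmetric matrix of squared correlations with unit
#'   diagonal.
#' @return an [LDInfo].
#' @export
ldInfo <- function(snps, r2) {
  dimnames(r2) <- list(snps, snps)
  new("LDInfo", snps = as.character(snps), r2 = r2)
}

#' Pairwise r-squared lookup
#'
#' Vectorized squared-correlation lookup. Pairs where either variant is
#' absent from the reference are treated as independent (`r2 = 0`), matching
#' PLINK's behaviour when a pair is missing from the panel; a warning
#' reports how many lookups fell back to 0.
#'
#' @param ld an [LDInfo].
#' @param a,b character vectors of variant ids (recycled to common length).
#' @return numeric vector of squared correlations in \[0, 1\].
#' @export
ldR2 <- function(ld, a, b) {
  stopifnot(is(ld, "LDInfo"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  ia <- match(a, ld@snps); ib <- match(b, ld@snps)
  out <- numeric(n)
  known <- !is.na(ia) & !is.na(ib)
  out[known] <- ld@r2[cbind(ia[known], ib[known])]
  if (any(!known))
    warning(sprintf("ldR2: %d pair(s) missing from the LD reference treated as r2 = 0",
                    sum(!known)))
  out
}
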