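## Binary result-cube format ("BCUB").
##
## Header: magic "BCUB"; three little-endian 64-bit integers m, t, p;
## three label tables (SNP ids, trait ids, coefficient names), each a
## 64-bit count followed by length-prefixed UTF-8 strings. Payload:
## m*t*p doubles for the effect cube B, m*t*p for the standard errors,
## m*t for the SNP-coefficient Wald statistics, all little-endian in R
## array order (SNP index fastest). Round trips are bit-identical.

.BCUB_MAGIC <- charToRaw("BCUB")

.writeLabels <- function(con, labels) {
  writeBin(.int64ToRaw(length(labels)), con)
  for (s in labels) {
    b <- charToRaw(enc2utf8(s))
    writeBin(.int64ToRaw(length(b)), con)
    writeBin(b, con)
  }
}

.readLabels <- function(con) {
  k <- .rawToInt64(readBin(con, "raw", 8))
  vapply(seq_len(k), function(i) {
    nb <- .rawToInt64(readBin(con, "raw", 8))
    rawToChar(readBin(con, "raw", nb))
  }, character(1))
}

#' Write a result cube to the binary cube format
#'
#' @param x a [GwasResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readCube()], [exportCubeTSV()]
#' @export
writeCube <- function(x, path) {
  stopifnot(is(x, "GwasResult"))
  con <- file(path, "wb")
  on.exit(close(con))
  m <- nrow(x); t <- ncol(x); p <- length(coefNames(x))
  writeBin(.BCUB_MAGIC, con)
  writeBin(.int64ToRaw(m), con)
  writeBin(.int64ToRaw(t), con)
  writeBin(.int64ToRaw(p), con)
  .writeLabels(con, snpIds(x))
  .writeLabels(con, traitIds(x))
  .writeLabels(con, coefNames(x))
  writeBin(as.numeric(effectArray(x)), con, size = 8, endian = "little")
  writeBin(as.numeric(seArray(x)), con, size = 8, endian = "little")
  writeBin(as.numeric(chiSquared(x)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a binary result cube
#'
#' @param path path of a file written by [writeCube()].
#' @return The reconstructed [GwasResult-class] (p-values are recomputed
#'   from the stored Wald statistics).
#' @export
readCube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, .BCUB_MAGIC))
    stop("not a BCUB cube file", call. = FALSE)
  m <- .rawToInt64(readBin(con, "raw", 8))
  t <- .rawToInt64(readBin(con, "raw", 8))
  p <- .rawToInt64(readBin(con, "raw", 8))
  snp_ids <- .readLabels(con)
  trait_ids <- .readLabels(con)
  coef_names <- .readLabels(con)
  if (length(snp_ids) != m || length(trait_ids) != t ||
      length(coef_names) != p)
    stop("cube label tables do not match the declared dimensions",
         call. = FALSE)
  Bv <- readBin(con, "double", m * t * p, size = 8, endian = "little")
  Sv <- readBin(con, "double", m * t * p, size = 8, endian = "little")
  if (length(Bv) < m * t * p || length(Sv) < m * t * p)
    stop("truncated cube payload", call. = FALSE)
  B <- array(Bv, dim = c(m, t, p))
  S <- array(Sv, dim = c(m, t, p))
  chi2v <- readBin(con, "double", m * t, size = 8, endian = "little")
  if (length(chi2v) < m * t)
    stop("truncated cube payload", call. = FALSE)
  chi2 <- matrix(chi2v, m, t)
  pval <- pchisq(chi2, 1, lower.tail = FALSE)
  .makeGwasResult(
    beta = lapply(seq_len(p), function(k) matrix(B[, , k], m, t)),
    se = lapply(seq_len(p), function(k) matrix(S[, , k], m, t)),
    chi2 = chi2, pvalue = pval,
    snp_ids = snp_ids, trait_ids = trait_ids, coef_names = coef_names)
}

#' Export a result cube as a long-format TSV
#'
#' One row per (SNP, trait, coefficient) with columns `snp_id`,
#' `trait_id`, `coefficient`, `beta`, `se`, `chi2`, `pvalue`. Numbers are
#' printed at 6 significant digits; degenerate cells appear as `NA`.
#'
#' @param x a [GwasResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportCubeTSV <- function(x, path) {
  df <- assocTable(x)
  for (col in c("beta", "se", "chi2", "pvalue")) {
    v <- df[[col]]
    v[is.nan(v)] <- NA
    df[[col]] <- ifelse(is.na(v), NA, signif(v, 6))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
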