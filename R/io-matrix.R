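## On-disk matrix formats.
##
## Two interchangeable layouts:
##   * delimited text (TSV): header row of column ids, first column the
##     sample id, missing values written "NA";
##   * raw binary ("MMG1"): magic bytes "MMG1", three little-endian 64-bit
##     integers (rows, cols, element size = 8), then row-major 64-bit
##     floats. Bit-exact round trips; no labels.

.MMG1_MAGIC <- charToRaw("MMG1")
.MMG1_HEADER_BYTES <- 4L + 3L * 8L

## 64-bit little-endian unsigned integers via raw bytes (exact to 2^53)
.int64ToRaw <- function(x) {
  x <- as.numeric(x)
  out <- raw(8)
  for (i in 1:8) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.rawToInt64 <- function(r) {
  sum(as.numeric(r) * 256^(0:7))
}

#' Write a matrix file
#'
#' @param x numeric matrix; row names are taken as sample ids for the text
#'   format (defaulting to `S1..Sn`).
#' @param path output path.
#' @param format `"tsv"` (delimited text with labels) or `"binary"` (the
#'   bit-exact `MMG1` layout, unlabeled).
#' @return `path`, invisibly.
#' @seealso [readMatrixFile()], [blockIterator()]
#' @export
writeMatrixFile <- function(x, path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  x <- as.matrix(x)
  if (format == "tsv") {
    ids <- rownames(x) %||% paste0("S", seq_len(nrow(x)))
    cols <- colnames(x) %||% paste0("C", seq_len(ncol(x)))
    df <- data.frame(id = ids, x, stringsAsFactors = FALSE,
                     check.names = FALSE)
    colnames(df) <- c("id", cols)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.MMG1_MAGIC, con)
    writeBin(.int64ToRaw(nrow(x)), con)
    writeBin(.int64ToRaw(ncol(x)), con)
    writeBin(.int64ToRaw(8), con)
    ## row-major: write the transpose's column-major stream
    writeBin(as.numeric(t(x)), con, size = 8, endian = "little")
  }
  invisible(path)
}

.isMMG1 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  identical(readBin(con, "raw", 4), .MMG1_MAGIC)
}

.readMMG1Header <- function(con) {
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, .MMG1_MAGIC))
    stop("not an MMG1 matrix file", call. = FALSE)
  r <- .rawToInt64(readBin(con, "raw", 8))
  c <- .rawToInt64(readBin(con, "raw", 8))
  es <- .rawToInt64(readBin(con, "raw", 8))
  if (es != 8)
    stop("MMG1 element size must be 8 bytes", call. = FALSE)
  list(nrow = r, ncol = c)
}

#' Read a matrix file
#'
#' Reads either format written by [writeMatrixFile()] (binary files are
#' recognized by their magic bytes) and applies role-specific validation.
#' Duplicate sample ids, non-numeric cells and payload/dimension mismatches
#' are errors; genotype dosages outside `[0, 2]` only warn (imputed dosages
#' may step outside the bounds) and are retained.
#'
#' @param path file path.
#' @param role one of `"generic"`, `"genotype"`, `"phenotype"`,
#'   `"covariate"`, `"kinship"`; controls validation. A kinship file must
#'   be square with matching row and column labels.
#' @return Numeric matrix; text files carry row (sample id) and column
#'   labels, binary files are unlabeled.
#' @export
readMatrixFile <- function(path,
                           role = c("generic", "genotype", "phenotype",
                                    "covariate", "kinship")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (.isMMG1(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    hd <- .readMMG1Header(con)
    expect <- .MMG1_HEADER_BYTES + 8 * hd$nrow * hd$ncol
    if (file.size(path) != expect)
      stop(sprintf("MMG1 dimension mismatch: header declares %d x %d (%d bytes) but file has %d bytes",
                   hd$nrow, hd$ncol, expect, file.size(path)), call. = FALSE)
    v <- readBin(con, "double", hd$nrow * hd$ncol, size = 8,
                 endian = "little")
    x <- matrix(v, nrow = hd$nrow, ncol = hd$ncol, byrow = TRUE)
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character")
    if (ncol(df) < 2)
      stop("matrix file must have an id column plus data columns",
           call. = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids))
      stop("duplicate sample ids in ", path, call. = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- is.na(num) & !(vals %in% c("NA", "NaN")) & !is.na(vals)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell at row %s, column %s: '%s'",
                   ids[idx[1]], colnames(vals)[idx[2]], vals[idx[1], idx[2]]),
           call. = FALSE)
    }
    x <- num
    dimnames(x) <- list(ids, colnames(vals))
  }
  if (role == "genotype" && any(is.finite(x) & (x < 0 | x > 2)))
    warning("genotype dosages outside [0, 2] retained (",
            sum(is.finite(x) & (x < 0 | x > 2)), " cells)")
  if (role == "kinship") {
    if (nrow(x) != ncol(x))
      stop("kinship file must be square", call. = FALSE)
    if (!is.null(rownames(x)) && !identical(rownames(x), colnames(x)))
      stop("kinship row and column ids differ", call. = FALSE)
  }
  x
}

#' Blocked column iterator over a genotype matrix
#'
#' Yields consecutive, non-overlapping column blocks covering all columns
#' exactly once and in order, without ever holding more than one block in
#' memory for file-backed input. Binary (`MMG1`) files are streamed with
#' per-row seeks so a block of `k` columns costs `n * k` resident entries;
#' a truncated file raises an error naming the failing byte offset. Text
#' files and in-memory matrices are held whole and sliced (the binary
#' layout is the streaming format).
#'
#' @param x numeric matrix, or path of a file readable by
#'   [readMatrixFile()].
#' @param blockCols positive number of columns per block.
#' @return A list with fields `n`, `ncol`, `colIds` and functions
#'   `nextBlock()` (returns `list(cols, values)` or `NULL` when
#'   exhausted) and `reset()`.
#' @examples
#' it <- blockIterator(matrix(1:20, 2), blockCols = 3)
#' it$nextBlock()$cols  # 1 2 3
#' @export
blockIterator <- function(x, blockCols = 256) {
  if (!is.numeric(blockCols) || length(blockCols) != 1 || blockCols < 1)
    stop("'blockCols' must be a positive integer", call. = FALSE)
  blockCols <- as.integer(blockCols)

  if (is.character(x) && length(x) == 1) {
    if (.isMMG1(x)) return(.mmg1Iterator(x, blockCols))
    x <- readMatrixFile(x, role = "genotype")
  }
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  pos <- 0L
  list(
    n = n, ncol = m, colIds = colnames(x), blockCols = blockCols,
    nextBlock = function() {
      if (pos >= m) return(NULL)
      cols <- (pos + 1L):min(pos + blockCols, m)
      pos <<- max(cols)
      .memAcquire("geno_block", n * length(cols))
      list(cols = cols, values = x[, cols, drop = FALSE])
    },
    reset = function() pos <<- 0L)
}

.mmg1Iterator <- function(path, blockCols) {
  con <- file(path, "rb")
  hd <- .readMMG1Header(con)
  close(con)
  n <- hd$nrow; m <- hd$ncol
  pos <- 0L
  list(
    n = n, ncol = m, colIds = NULL, blockCols = blockCols,
    nextBlock = function() {
      if (pos >= m) return(NULL)
      cols <- (pos + 1L):min(pos + blockCols, m)
      pos <<- max(cols)
      k <- length(cols)
      con <- file(path, "rb")
      on.exit(close(con))
      blk <- matrix(NA_real_, n, k)
      for (i in seq_len(n)) {
        off <- .MMG1_HEADER_BYTES + 8 * ((i - 1) * m + (cols[1] - 1))
        seek(con, off)
        got <- readBin(con, "double", k, size = 8, endian = "little")
        if (length(got) < k)
          stop(sprintf("truncated matrix file %s at byte offset %d",
                       path, off + 8 * length(got)), call. = FALSE)
        blk[i, ] <- got
      }
      .memAcquire("geno_block", n * k)
      list(cols = cols, values = blk)
    },
    reset = function() pos <<- 0L)
}
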