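## internal helpers: argument checks, seeding, sample-id alignment

.checkMatrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (anyNA(x) && name != "phenotypes")
    stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  invisible(x)
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its admissible range %s%g, %g%s",
                 name, x, if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

## Derive a per-component 31-bit seed from a master seed and a stream label,
## so that e.g. adding traits never perturbs the genotype stream.
.componentSeed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  s <- (as.numeric(seed) * 48271 + h) %% 2147483647
  as.integer(s) + 1L
}

## Strict sample alignment: identical ids in identical order, never a reorder.
.checkSampleOrder <- function(ids_a, ids_b, what_a, what_b) {
  if (length(ids_a) != length(ids_b))
    stop(sprintf("sample count mismatch: %s has %d samples, %s has %d",
                 what_a, length(ids_a), what_b, length(ids_b)), call. = FALSE)
  if (!identical(as.character(ids_a), as.character(ids_b)))
    stop(sprintf(paste0("sample ids of %s and %s differ or are ordered ",
                        "differently; inputs are never reordered implicitly"),
                 what_a, what_b), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
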