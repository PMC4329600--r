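## Lightweight run-time instrumentation shared by both scan engines.
##
## Two counters are kept: multiply-add totals per algorithmic phase, and the
## number of matrix entries currently resident in the engine's working set.
## The memory counter tracks what the blocked algorithms are designed to keep
## live (the n x n factor, the covariate block, resident trait columns, and
## the current genotype block), so its peak can be checked against
## memoryBudget().

.instr <- new.env(parent = emptyenv())

#' Reset the operation and memory instrumentation counters
#'
#' Both scan engines count the multiply-add operations they perform per
#' algorithmic phase (factorization, whitening, rotation, per-cell solves)
#' and the peak number of matrix entries resident at once. Counters
#' accumulate across calls until reset.
#'
#' @return Invisibly, `NULL`.
#' @seealso [instrOps()], [instrPeakEntries()], [memoryBudget()]
#' @export
instrReset <- function() {
  .instr$ops <- new.env(parent = emptyenv())
  .instr$cols <- new.env(parent = emptyenv())
  .instr$cur <- 0
  .instr$peak <- 0
  .instr$tags <- new.env(parent = emptyenv())
  invisible(NULL)
}

.opAdd <- function(phase, n) {
  prev <- get0(phase, envir = .instr$ops, ifnotfound = 0)
  assign(phase, prev + n, envir = .instr$ops)
  invisible(NULL)
}

## count of columns processed by a phase (e.g. rotations performed)
.colAdd <- function(phase, k = 1) {
  prev <- get0(phase, envir = .instr$cols, ifnotfound = 0)
  assign(phase, prev + k, envir = .instr$cols)
  invisible(NULL)
}

.memAcquire <- function(tag, entries) {
  if (!is.null(get0(tag, envir = .instr$tags, ifnotfound = NULL)))
    .memRelease(tag)
  assign(tag, entries, envir = .instr$tags)
  .instr$cur <- .instr$cur + entries
  if (.instr$cur > .instr$peak) .instr$peak <- .instr$cur
  invisible(NULL)
}

.memRelease <- function(tag) {
  entries <- get0(tag, envir = .instr$tags, ifnotfound = NULL)
  if (!is.null(entries)) {
    .instr$cur <- .instr$cur - entries
    rm(list = tag, envir = .instr$tags)
  }
  invisible(NULL)
}

#' Read the per-phase operation counters
#'
#' @return Named numeric vector of multiply-add counts accumulated since the
#'   last [instrReset()], one element per phase (e.g. `"whiten"`,
#'   `"rotate_snps"`, `"rotate_traits"`, `"wls"`, `"ols_update"`,
#'   `"chol_factor"`, `"eigen"`).
#' @export
instrOps <- function() {
  nms <- ls(.instr$ops)
  vapply(nms, function(nm) get(nm, envir = .instr$ops), numeric(1))
}

#' Read the per-phase column counters
#'
#' Counts how many columns each phase processed (e.g. how many genotype or
#' trait columns were rotated), independent of their length.
#'
#' @return Named numeric vector of column counts since the last [instrReset()].
#' @export
instrColCounts <- function() {
  nms <- ls(.instr$cols)
  vapply(nms, function(nm) get(nm, envir = .instr$cols), numeric(1))
}

#' Peak resident working-set size observed by the instrumentation
#'
#' @return Peak number of matrix entries simultaneously resident in the
#'   engines' tracked working set since the last [instrReset()].
#' @export
instrPeakEntries <- function() .instr$peak
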