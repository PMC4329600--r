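## Cost model and engine selection.
##
## The model predicts multiply-add totals with the same per-phase counting
## convention the instrumented engines use, so predictions and measured
## counts agree on instances small enough to run. Constants below are the
## per-column / per-cell counts of the implementation:
##   - Cholesky factorization of an n x n matrix:    n^3 / 3
##   - symmetric eigendecomposition (with vectors):  (10/3) n^3
##     (an order of magnitude above the Cholesky count, reflecting the
##      practical cost ratio of the two factorizations)
##   - triangular solve per column (whitening):      n (n + 1) / 2
##   - dense rotation per column:                    n^2
##   - covariate-reuse OLS update per SNP:           (p + 1) n + p^2
##   - weighted LS per grid cell:                    (p + 2) n + p^2
##   - one likelihood evaluation in step one:        (p + 2) n

.EIG_FACTOR_MADDS <- function(n) (10 / 3) * n^3
.CHOL_FACTOR_MADDS <- function(n) n^3 / 3
.WHITEN_COL_MADDS <- function(n) n * (n + 1) / 2
.ROTATE_COL_MADDS <- function(n) n^2
.OLS_CELL_MADDS <- function(n, p) (p + 1) * n + p^2
.WLS_CELL_MADDS <- function(n, p) (p + 2) * n + p^2

#' Predicted operation and memory costs of the scan engines
#'
#' Models the multiply-add totals of the Cholesky-whitening engine and the
#' eigen-rotation engine for a study with `n` samples, `m` SNPs, `t` traits
#' and `p` fixed effects, including the shared step-one variance-component
#' estimation (one eigendecomposition plus `t * v` likelihood
#' evaluations). The Cholesky engine pays a factorization and a whitening
#' sweep per trait; the eigen engine reuses the step-one eigendecomposition,
#' rotates each genotype and trait column once, and fills the grid with
#' weighted least-squares cells. The dominant terms reproduce the
#' asymptotic costs O(mpn^2) (single-trait), O(tmn) (t > n) and O(mn^2)
#' (n > t).
#'
#' @param n,m,t,p problem dimensions.
#' @param v likelihood-evaluation budget per trait in step one (default 50).
#' @return A `data.frame` with one row per algorithm: `algorithm`, `flops`
#'   (modeled multiply-adds) and `memory_entries` (minimum working set,
#'   `n^2 + (2 + p) n`).
#' @examples
#' predictCosts(n = 1000, m = 1e6, t = 1, p = 3)
#' @export
predictCosts <- function(n, m, t, p, v = 50) {
  stopifnot(n >= 1, m >= 1, t >= 0, p >= 1, v >= 1)
  q <- p - 1  # covariate columns
  shared <- .EIG_FACTOR_MADDS(n) + t * v * ((q + 3) * n)

  chol_flops <- shared + t * (
    .CHOL_FACTOR_MADDS(n) +
      (m + q + 1) * .WHITEN_COL_MADDS(n) +       # SNPs, covariates, trait
      m * .OLS_CELL_MADDS(n, p))

  eig_flops <- shared +                           # eigendecomposition reused
    (m + t + q) * .ROTATE_COL_MADDS(n) +          # each column rotated once
    t * (q * (q + 1) / 2 + q + 1) * n +           # per-trait cross-products
    m * t * .WLS_CELL_MADDS(n, p)

  mem <- n^2 + (2 + p) * n
  data.frame(
    algorithm = c("chol", "eig"),
    flops = c(chol_flops, eig_flops),
    memory_entries = c(mem, mem),
    stringsAsFactors = FALSE)
}

#' Select the scan engine with the smaller predicted cost
#'
#' Compares the modeled operation counts of the two engines and returns the
#' cheaper one. For genome-scale marker counts the Cholesky engine wins for
#' single-trait (and very-few-trait) scans and the eigen engine wins beyond
#' a handful of traits; the crossover in `t` is single and monotone because
#' both models are affine in `t` with the Cholesky slope far steeper.
#'
#' @param n,m,t,p problem dimensions.
#' @param v step-one likelihood budget (default 50).
#' @return `"chol"` or `"eig"`.
#' @examples
#' selectAlgorithm(n = 1000, m = 1e6, t = 1, p = 3)     # "chol"
#' selectAlgorithm(n = 1000, m = 1e6, t = 1000, p = 3)  # "eig"
#' @export
selectAlgorithm <- function(n, m, t, p, v = 50) {
  costs <- predictCosts(n, m, t, p, v)
  costs$algorithm[which.min(costs$flops)]
}

#' Memory budget of a blocked scan
#'
#' The engines keep the n x n kinship-derived factor plus `k` resident SNP
#' and trait columns and the `p` fixed-effect columns in memory:
#' `n^2 + (k + p) n` entries. `k = 2` (one SNP, one trait) is the minimum
#' footprint. Instrumented peak working-set sizes are checked against this
#' bound.
#'
#' @param n sample size.
#' @param p number of fixed effects.
#' @param k number of SNP and trait columns resident at once (>= 2).
#' @return The entry count `n^2 + (k + p) n`.
#' @examples
#' memoryBudget(10, 3, 2)  # 150
#' @export
memoryBudget <- function(n, p, k) {
  stopifnot(n >= 1, p >= 1)
  if (!is.numeric(k) || length(k) != 1 || k < 2)
    stop("'k' must be at least 2: one SNP and one trait resident",
         call. = FALSE)
  n^2 + (k + p) * n
}
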