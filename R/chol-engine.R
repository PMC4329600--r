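## Cholesky-whitening scan engine for single-trait analyses.
##
## One Cholesky factorization of the trait covariance M per trait converts
## every generalized least-squares problem of the scan into ordinary least
## squares on whitened data. All cross-products that involve only the
## covariate block are computed once and reused for every SNP, so a SNP
## costs O(np) instead of O(np^2).

#' Cholesky factor of a trait covariance matrix
#'
#' @param M symmetric positive-definite matrix (e.g. from
#'   [buildCovariance()]).
#' @return Lower-triangular `L` with `L %*% t(L) = M` and positive
#'   diagonal. Fails with the index of the first non-positive pivot when
#'   `M` is not positive definite.
#' @examples
#' cholCovariance(matrix(c(4, 2, 2, 5), 2))  # [[2,0],[1,2]]
#' @export
cholCovariance <- function(M) {
  M <- as.matrix(M)
  .checkMatrix(M, "M")
  if (nrow(M) != ncol(M)) stop("'M' must be square", call. = FALSE)
  R <- tryCatch(chol(M), error = function(e) e)
  if (inherits(R, "error")) {
    piv <- sub(".*order (\\d+).*", "\\1", conditionMessage(R))
    stop(sprintf("covariance matrix is not positive definite (pivot %s)",
                 piv), call. = FALSE)
  }
  .opAdd("chol_factor", nrow(M)^3 / 3)
  t(R)
}

#' Whiten a matrix with a Cholesky factor
#'
#' Solves `L W = A` by forward substitution, column by column (the inverse
#' of `L` is never formed). For `L` from [cholCovariance()] this removes
#' the covariance structure: `crossprod(W)` equals `t(A) %*% solve(M, A)`.
#'
#' @param L lower-triangular Cholesky factor.
#' @param A n x k matrix (or length-n vector) to whiten.
#' @return The whitened n x k matrix (or vector when `A` is a vector).
#' @export
whitenMatrix <- function(L, A) {
  n <- nrow(L)
  vec <- is.null(dim(A))
  A <- as.matrix(A)
  if (nrow(A) != n)
    stop(sprintf("dimension mismatch: L is %d x %d, A has %d rows",
                 n, ncol(L), nrow(A)), call. = FALSE)
  W <- A
  ## per-column solves keep results bit-identical across any blocking
  for (j in seq_len(ncol(A)))
    W[, j] <- forwardsolve(L, A[, j])
  .opAdd("whiten", ncol(A) * n * (n + 1) / 2)
  .colAdd("whiten_cols", ncol(A))
  if (vec) as.numeric(W) else W
}

#' Per-trait whitened scan state
#'
#' Precomputes everything in the single-trait scan that does not depend on
#' the SNP: the Cholesky factor `L` of the trait covariance, the whitened
#' covariates and trait, and the covariate-only cross-products (held as the
#' Cholesky factor of `X_L' M^-1 X_L`). These are reused verbatim for every
#' SNP of the scan.
#'
#' @param XL n x (p-1) covariate matrix including the intercept column.
#' @param y numeric trait vector.
#' @param M positive-definite trait covariance from [buildCovariance()].
#' @return A list with components `L`, `XL_w`, `y_w`, `RLL` (upper
#'   Cholesky factor of the covariate cross-product matrix) and `sLy`,
#'   consumed by [scanSnp()].
#' @export
whitenScanState <- function(XL, y, M) {
  L <- cholCovariance(M)
  XL_w <- whitenMatrix(L, XL)
  y_w <- whitenMatrix(L, y)
  SLL <- crossprod(XL_w)
  RLL <- chol(SLL)
  list(L = L, XL_w = XL_w, y_w = y_w, RLL = RLL,
       sLy = as.numeric(crossprod(XL_w, y_w)))
}

## Solve the p x p normal equations for [X_L | x] given the cached Cholesky
## factor of X_L'X_L plus the new cross-products. Returns NULL when the SNP
## column is (numerically) collinear with the covariates.
.rankOneSolve <- function(RLL, sLy, sLx, sxx, sxy, tol = 1e-10) {
  q <- ncol(RLL)
  u <- backsolve(RLL, sLx, transpose = TRUE)
  d <- sxx - sum(u^2)
  if (!is.finite(d) || d <= tol * max(sxx, 1e-300)) return(NULL)
  r <- sqrt(d)
  Rfull <- rbind(cbind(RLL, u), c(rep(0, q), r))
  rhs <- c(sLy, sxy)
  z <- backsolve(Rfull, rhs, transpose = TRUE)
  beta <- backsolve(Rfull, z)
  cov <- chol2inv(Rfull)
  se <- sqrt(diag(cov))
  list(beta = beta, se = se)
}

#' Test one whitened SNP column against the cached scan state
#'
#' Assembles the p x p normal equations from the cached covariate
#' cross-products plus the `2p - 1` new cross-products involving the SNP
#' column (O(np) work, never O(np^2)), solves for the effect vector and its
#' covariance, and returns the association record. A SNP collinear with
#' the covariates (e.g. monomorphic, with an intercept present) yields a
#' degenerate record with `NaN` estimates rather than an error.
#'
#' @param state output of [whitenScanState()].
#' @param xr_w SNP column whitened with the same Cholesky factor
#'   (see [whitenMatrix()]).
#' @param y_w whitened response; defaults to the trait cached in `state`.
#' @return List with `beta`, `se` (length p, SNP last), `chi2`, `pvalue`
#'   and the logical flag `degenerate`.
#' @export
scanSnp <- function(state, xr_w, y_w = state$y_w) {
  n <- length(xr_w)
  q <- ncol(state$XL_w)
  sLx <- as.numeric(crossprod(state$XL_w, xr_w))
  sxx <- sum(xr_w^2)
  sxy <- sum(xr_w * y_w)
  .opAdd("ols_update", (q + 2) * n + (q + 1)^2)
  sol <- .rankOneSolve(state$RLL, state$sLy, sLx, sxx, sxy)
  p <- q + 1L
  if (is.null(sol))
    return(list(beta = rep(NaN, p), se = rep(NaN, p),
                chi2 = NaN, pvalue = NaN, degenerate = TRUE))
  chi2 <- (sol$beta[p] / sol$se[p])^2
  list(beta = sol$beta, se = sol$se, chi2 = chi2,
       pvalue = pchisq(chi2, 1, lower.tail = FALSE), degenerate = FALSE)
}

#' Single-trait genome-wide scan by Cholesky whitening
#'
#' Builds the trait covariance from the step-one variance components,
#' factors it once, whitens the covariates and the trait, then streams the
#' genotype matrix in column blocks: each SNP column is whitened and tested
#' with cached covariate cross-products. Output is independent of the
#' block size. Collinear (e.g. monomorphic) SNPs yield `NaN` records and
#' the scan continues.
#'
#' @param genotypes n x m dosage matrix, or the path of a matrix file
#'   readable by [blockIterator()].
#' @param y numeric trait vector of length n.
#' @param XL n x (p-1) covariate matrix including the intercept column.
#' @param phi the study [KinshipMatrix-class] (or plain matrix).
#' @param ve the trait's [VarianceEstimate-class] from [estimateH2()].
#' @param blockSize number of genotype columns per streamed block
#'   (default 256).
#' @param traitId trait label for the result (default `"trait1"`).
#' @return A [GwasResult-class] with one trait column.
#' @seealso [runEigGwas()] for the multi-trait engine, [glsSolve()] for the
#'   reference solver this engine reproduces.
#' @export
runCholGwas <- function(genotypes, y, XL, phi, ve, blockSize = 256,
                        traitId = "trait1") {
  stopifnot(is(ve, "VarianceEstimate"))
  XL <- as.matrix(XL)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(XL) != n)
    stop("sample count mismatch between y and XL", call. = FALSE)
  phiV <- if (is(phi, "KinshipMatrix")) phi@values else as.matrix(phi)
  if (!all(dim(phiV) == c(n, n)))
    stop("sample count mismatch between y and phi", call. = FALSE)
  it <- blockIterator(genotypes, blockSize)
  if (it$n != n)
    stop("sample count mismatch between genotypes and y", call. = FALSE)

  q <- ncol(XL)
  coef_names <- c(colnames(XL) %||% paste0("cov", seq_len(q)), "snp")
  .memAcquire("chol_factor", n * n)
  .memAcquire("covariates_w", n * q)
  .memAcquire("trait_w", n)
  M <- buildCovariance(phiV, ve@sigma2, ve@h2)
  state <- whitenScanState(XL, y, M)

  m <- it$ncol
  p <- q + 1L
  beta <- matrix(NA_real_, m, p)
  se <- matrix(NA_real_, m, p)
  chi2 <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  repeat {
    blk <- it$nextBlock()
    if (is.null(blk)) break
    for (j in seq_along(blk$cols)) {
      xr_w <- whitenMatrix(state$L, blk$values[, j])
      rec <- scanSnp(state, xr_w)
      i <- blk$cols[j]
      beta[i, ] <- rec$beta
      se[i, ] <- rec$se
      chi2[i] <- rec$chi2
      pval[i] <- rec$pvalue
    }
    .memRelease("geno_block")
  }
  .memRelease("chol_factor"); .memRelease("covariates_w"); .memRelease("trait_w")

  snp_ids <- it$colIds %||% paste0("snp", seq_len(m))
  .makeGwasResult(
    beta = lapply(seq_len(p), function(k) matrix(beta[, k], m, 1)),
    se = lapply(seq_len(p), function(k) matrix(se[, k], m, 1)),
    chi2 = matrix(chi2, m, 1), pvalue = matrix(pval, m, 1),
    snp_ids = snp_ids, trait_ids = traitId, coef_names = coef_names,
    varianceEstimates = list(ve))
}
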