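## Eigen-rotation scan engine for multi-trait analyses.
##
## The kinship matrix is eigendecomposed once; its eigenvectors rotate the
## covariates, every genotype column and every trait column exactly once.
## In the rotated basis each trait covariance is diagonal, so every cell of
## the SNP x trait grid is an inexpensive weighted least-squares problem
## with per-sample weights derived by shifting and scaling the kinship
## eigenvalues.

#' Rotate a matrix into the kinship eigenbasis
#'
#' Multiplies by the transpose of the kinship eigenvector matrix (`V' A`).
#' The rotation is orthogonal, so column norms are preserved; each column
#' of a study needs rotating only once.
#'
#' @param ek an [EigenKinship-class].
#' @param A n x k matrix (or length-n vector).
#' @return The rotated matrix (or vector).
#' @export
rotateMatrix <- function(ek, A) {
  stopifnot(is(ek, "EigenKinship"))
  V <- ek@vectors
  vec <- is.null(dim(A))
  A <- as.matrix(A)
  if (nrow(A) != nrow(V))
    stop(sprintf("dimension mismatch: eigenvectors are %d x %d, A has %d rows",
                 nrow(V), ncol(V), nrow(A)), call. = FALSE)
  n <- nrow(V)
  R <- A
  ## per-column products keep results bit-identical across any blocking
  for (j in seq_len(ncol(A)))
    R[, j] <- crossprod(V, A[, j])
  .opAdd("rotate", ncol(A) * n^2)
  if (vec) as.numeric(R) else R
}

#' Weighted least squares with per-sample weights
#'
#' Solves the diagonal-covariance problem
#' \eqn{b = (X' W X)^{-1} X' W y}, `W = diag(w)`, the per-cell solve of the
#' eigen-rotation engine. Equivalent to [glsSolve()] with `M = diag(1/w)`.
#'
#' @param X_rot n x p design matrix (rotated).
#' @param y_rot length-n response (rotated).
#' @param w length-n vector of positive weights.
#' @param rescale rescale the coefficient covariance by the residual mean
#'   square (default `FALSE`, matching [glsSolve()]).
#' @return List with `beta`, `se` and `cov` as in [glsSolve()].
#' @export
wlsSolve <- function(X_rot, y_rot, w, rescale = FALSE) {
  X_rot <- as.matrix(X_rot)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be finite and positive", call. = FALSE)
  if (length(w) != nrow(X_rot) || length(y_rot) != nrow(X_rot))
    stop("dimension mismatch between X_rot, y_rot and w", call. = FALSE)
  sw <- sqrt(w)
  .whitenedLS(X_rot * sw, y_rot * sw, rescale = rescale,
              colnames = colnames(X_rot))
}

## Per-trait state in the rotated basis: weights and covariate-only
## cross-products, reused for every SNP of that trait.
.traitState <- function(XL_rot, y_rot, lam, sigma2, h2) {
  w <- 1 / shiftedEigenvalues(lam, sigma2, h2)
  wXL <- XL_rot * w
  SLL <- crossprod(XL_rot, wXL)
  RLL <- tryCatch(chol(SLL), error = function(e)
    stop("covariate block is singular in the rotated basis", call. = FALSE))
  q <- ncol(XL_rot)
  .opAdd("wls_setup", (q * (q + 1) / 2 + q + 1) * length(w))
  list(w = w, RLL = RLL, sLy = as.numeric(crossprod(wXL, y_rot)),
       y_rot = y_rot)
}

## One (rotated SNP, trait) cell.
.wlsCell <- function(ts, XL_rot, xr_rot) {
  n <- length(xr_rot)
  q <- ncol(XL_rot)
  wx <- ts$w * xr_rot
  sLx <- as.numeric(crossprod(XL_rot, wx))
  sxx <- sum(xr_rot * wx)
  sxy <- sum(wx * ts$y_rot)
  .opAdd("wls", (q + 3) * n + (q + 1)^2)
  sol <- .rankOneSolve(ts$RLL, ts$sLy, sLx, sxx, sxy)
  p <- q + 1L
  if (is.null(sol))
    return(list(beta = rep(NaN, p), se = rep(NaN, p),
                chi2 = NaN, pvalue = NaN))
  chi2 <- (sol$beta[p] / sol$se[p])^2
  list(beta = sol$beta, se = sol$se, chi2 = chi2,
       pvalue = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Multi-trait genome-wide scan by eigen rotation
#'
#' Runs the full SNP x trait grid of mixed-model association tests.
#' The kinship is eigendecomposed once; the covariates, every trait column
#' and every genotype column are rotated exactly once; each (SNP, trait)
#' cell is then a weighted least-squares solve with that trait's
#' shifted-and-scaled eigenvalue weights, reusing the covariate
#' cross-products cached per trait. Results equal the dense-covariance GLS
#' solution cell for cell.
#'
#' Genotypes are streamed in column blocks (rotated block resident,
#' traits swept per block); output is independent of the block size.
#'
#' @param genotypes n x m dosage matrix, or a matrix-file path accepted by
#'   [blockIterator()].
#' @param phenotypes n x t matrix of complete trait values (impute first;
#'   see [meanImpute()]).
#' @param XL n x (p-1) covariate matrix including the intercept column.
#' @param phi the study [KinshipMatrix-class] (or plain matrix).
#' @param ves list of per-trait [VarianceEstimate-class] objects from
#'   [estimateH2()], one per phenotype column.
#' @param blockSize genotype columns per streamed block (default 256).
#' @param ek optional precomputed [EigenKinship-class] of `phi`, to avoid
#'   repeating the eigendecomposition.
#' @return A [GwasResult-class] with the full m x t x p cube.
#' @seealso [runCholGwas()], [selectAlgorithm()]
#' @export
runEigGwas <- function(genotypes, phenotypes, XL, phi, ves,
                       blockSize = 256, ek = NULL) {
  phenotypes <- as.matrix(phenotypes)
  if (anyNA(phenotypes))
    stop("phenotypes have missing values; impute first (see meanImpute)",
         call. = FALSE)
  XL <- as.matrix(XL)
  n <- nrow(phenotypes)
  t_n <- ncol(phenotypes)
  if (nrow(XL) != n)
    stop("sample count mismatch between phenotypes and XL", call. = FALSE)
  if (!is.list(ves) || length(ves) != t_n ||
      !all(vapply(ves, is, logical(1), "VarianceEstimate")))
    stop("'ves' must be a list of one VarianceEstimate per trait",
         call. = FALSE)
  if (is.null(ek)) {
    phiV <- if (is(phi, "KinshipMatrix")) phi@values else as.matrix(phi)
    if (!all(dim(phiV) == c(n, n)))
      stop("sample count mismatch between phenotypes and phi", call. = FALSE)
    ek <- eigenKinship(phi)
  }
  it <- blockIterator(genotypes, blockSize)
  if (it$n != n)
    stop("sample count mismatch between genotypes and phenotypes",
         call. = FALSE)

  q <- ncol(XL)
  p <- q + 1L
  m <- it$ncol
  coef_names <- c(colnames(XL) %||% paste0("cov", seq_len(q)), "snp")
  lam <- ek@values

  .memAcquire("eigenvectors", n * n)
  .memAcquire("covariates_rot", n * q)
  XL_rot <- rotateMatrix(ek, XL)
  .colAdd("rotate_covariate_cols", q)

  ## all trait columns stay resident (rotated once each)
  .memAcquire("traits_rot", n * t_n)
  Y_rot <- rotateMatrix(ek, phenotypes)
  .colAdd("rotate_trait_cols", t_n)

  ## per-trait weights are recomputed from the shared eigenvalues (O(n))
  states <- lapply(seq_len(t_n), function(j)
    .traitState(XL_rot, Y_rot[, j], lam, ves[[j]]@sigma2, ves[[j]]@h2))

  beta <- lapply(seq_len(p), function(k) matrix(NA_real_, m, t_n))
  se <- lapply(seq_len(p), function(k) matrix(NA_real_, m, t_n))
  chi2 <- matrix(NA_real_, m, t_n)
  pval <- matrix(NA_real_, m, t_n)

  repeat {
    blk <- it$nextBlock()
    if (is.null(blk)) break
    ## rotate the genotype block in place, one column each, exactly once
    G_rot <- rotateMatrix(ek, blk$values)
    .colAdd("rotate_snp_cols", ncol(G_rot))
    for (j in seq_len(t_n)) {
      ts <- states[[j]]
      for (c in seq_along(blk$cols)) {
        rec <- .wlsCell(ts, XL_rot, G_rot[, c])
        i <- blk$cols[c]
        for (k in seq_len(p)) {
          beta[[k]][i, j] <- rec$beta[k]
          se[[k]][i, j] <- rec$se[k]
        }
        chi2[i, j] <- rec$chi2
        pval[i, j] <- rec$pvalue
      }
    }
    .memRelease("geno_block")
  }
  .memRelease("eigenvectors"); .memRelease("covariates_rot")
  .memRelease("traits_rot")

  snp_ids <- it$colIds %||% paste0("snp", seq_len(m))
  trait_ids <- colnames(phenotypes) %||% paste0("trait", seq_len(t_n))
  .makeGwasResult(beta = beta, se = se, chi2 = chi2, pvalue = pval,
                  snp_ids = snp_ids, trait_ids = trait_ids,
                  coef_names = coef_names, varianceEstimates = ves)
}

#' Measure per-phase operation counts on a simulated instance
#'
#' Runs both scan engines, instrumented, on a synthetic dataset of the
#' requested dimensions and returns the multiply-add totals actually
#' counted per phase. Useful for verifying the scaling behaviour the cost
#' model predicts (rotation linear in the number of columns, the
#' weighted-least-squares grid linear in the number of traits, whitening
#' quadratic in the sample size).
#'
#' @param n,m,t,p problem dimensions: samples, SNPs, traits, fixed effects.
#' @param blockSize genotype block size for the streamed scans.
#' @param seed seed for the simulated instance.
#' @return A list with elements `eig` and `chol`, each a named numeric
#'   vector of per-phase multiply-add counts, plus `cols`, the per-phase
#'   column counts (rotations and whitenings performed).
#' @export
countOperations <- function(n, m, t, p, blockSize = 64, seed = 1) {
  cfg <- simConfig(n = n, m = m, t = t, p = p, seed = seed)
  dat <- simulateDataset(cfg)
  ek <- eigenKinship(dat$phi)
  ves <- lapply(seq_len(t), function(j)
    estimateH2(dat$phenotypes[, j], dat$XL, ek))

  instrReset()
  runEigGwas(dat$genotypes, dat$phenotypes, dat$XL, dat$phi, ves,
             blockSize = blockSize, ek = ek)
  eig_ops <- instrOps()
  eig_cols <- instrColCounts()

  instrReset()
  for (j in seq_len(t))
    runCholGwas(dat$genotypes, dat$phenotypes[, j], dat$XL, dat$phi,
                ves[[j]], blockSize = blockSize)
  chol_ops <- instrOps()

  instrReset()
  list(eig = eig_ops, chol = chol_ops, cols = eig_cols)
}
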