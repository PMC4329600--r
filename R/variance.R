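#' Eigendecomposition of the kinship matrix
#'
#' Computed once per study and reused everywhere the spectrum of the
#' kinship matrix is needed: variance-component estimation for every trait
#' and the eigen-rotation scan engine. Eigenvalues are returned in
#' descending order; values mildly below zero (within `-1e-8` of the
#' largest eigenvalue, as arise in empirical kinships) are clipped to zero
#' with a warning.
#'
#' @param phi a [KinshipMatrix-class] or a symmetric numeric matrix.
#' @return An [EigenKinship-class] with \eqn{\Phi = V \Lambda V'}.
#' @examples
#' ek <- eigenKinship(matrix(c(1, 0.5, 0.5, 1), 2))
#' eigenValues(ek)  # 1.5, 0.5
#' @export
eigenKinship <- function(phi) {
  ids <- NULL
  v <- if (is(phi, "KinshipMatrix")) {
    ids <- phi@sampleIds
    phi@values
  } else phi
  .checkMatrix(v, "phi")
  if (nrow(v) != ncol(v)) stop("'phi' must be square", call. = FALSE)
  scale <- max(abs(v), 1)
  if (max(abs(v - t(v))) > 1e-8 * scale)
    stop("'phi' is not symmetric to within 1e-8", call. = FALSE)
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  lam <- e$values
  lmax <- max(abs(lam), 1e-300)
  if (min(lam) < -1e-8 * lmax)
    warning(sprintf("clipping %d negative eigenvalue(s), smallest %.3g",
                    sum(lam < 0), min(lam)))
  lam[lam < 0] <- 0
  .opAdd("eigen", (10 / 3) * nrow(v)^3)
  new("EigenKinship", values = lam, vectors = e$vectors,
      sampleIds = ids %||% paste0("S", seq_len(nrow(v))))
}

#' Eigenvalues of the trait covariance from the kinship spectrum
#'
#' Because \eqn{M = \sigma^2 (h^2 \Phi + (1-h^2) I)} shares eigenvectors
#' with the kinship matrix, its eigenvalues follow by shifting and scaling
#' the kinship eigenvalues: \eqn{d_i = \sigma^2 (h^2 \lambda_i + 1 - h^2)}.
#'
#' @param ek an [EigenKinship-class], or a numeric vector of kinship
#'   eigenvalues.
#' @param sigma2 total trait variance, > 0.
#' @param h2 heritability in `[0, 1)`.
#' @return Vector of positive covariance eigenvalues.
#' @export
shiftedEigenvalues <- function(ek, sigma2, h2) {
  lam <- if (is(ek, "EigenKinship")) ek@values else as.numeric(ek)
  .checkScalar(sigma2, "sigma2", lower = 0, open_lower = TRUE)
  .checkScalar(h2, "h2", lower = 0, upper = 1, open_upper = TRUE)
  sigma2 * (h2 * lam + (1 - h2))
}

#' Profile log-likelihood of the heritability under the null model
#'
#' For data rotated by the kinship eigenvectors, the trait covariance is
#' diagonal with entries proportional to \eqn{w_i = h^2 \lambda_i + 1 -
#' h^2}. At a candidate `h2` this function fits the covariates by weighted
#' least squares (weights `1/w`), profiles out the total variance as
#' \eqn{\hat\sigma^2 = \sum r_i^2 / w_i / n} (maximum likelihood) and
#' returns the profiled Gaussian log-likelihood
#' \eqn{-\tfrac12 [n \log(2\pi\hat\sigma^2) + \sum \log w_i + n]}.
#'
#' With `reml = TRUE` the restricted likelihood is used instead: the
#' variance is profiled with divisor `n - p` and the criterion carries the
#' additional \eqn{\log|X' W X|} term.
#'
#' @param h2 candidate heritability in `[0, 1)`.
#' @param y_rot rotated response `V' y`.
#' @param XL_rot rotated covariate matrix `V' X_L`.
#' @param eigenvalues kinship eigenvalues (same rotation).
#' @param reml use the restricted likelihood (default `FALSE`).
#' @return List with `loglik`, `sigma2` (profiled variance) and `beta`
#'   (covariate effects at this `h2`).
#' @export
profileLoglik <- function(h2, y_rot, XL_rot, eigenvalues, reml = FALSE) {
  .checkScalar(h2, "h2", lower = 0, upper = 1, open_upper = TRUE)
  XL_rot <- as.matrix(XL_rot)
  n <- length(y_rot); p <- ncol(XL_rot)
  if (nrow(XL_rot) != n || length(eigenvalues) != n)
    stop("rotated inputs have inconsistent lengths", call. = FALSE)
  w <- h2 * eigenvalues + (1 - h2)
  if (any(w <= 0)) stop("non-positive covariance weight", call. = FALSE)
  sw <- 1 / sqrt(w)
  Xs <- XL_rot * sw
  ys <- y_rot * sw
  fit <- .whitenedLS(Xs, ys, colnames = colnames(XL_rot))
  resid <- ys - Xs %*% fit$beta
  rss <- sum(resid^2)
  .opAdd("loglik_eval", (p + 3) * n)
  if (reml) {
    s2 <- rss / (n - p)
    XtWX <- crossprod(Xs)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                    determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
  }
  list(loglik = as.numeric(ll), sigma2 = s2, beta = fit$beta)
}

#' Estimate per-trait variance components (step one of the two-step scan)
#'
#' Maximizes the profile log-likelihood of the heritability under the
#' covariates-only mixed model, using the shared kinship eigendecomposition
#' so that each trait costs only O(v n) likelihood work after the one-time
#' O(n^3) spectral factorization. The search is a coarse grid of 21 points
#' on `[0, 1 - 1e-6]` followed by bounded one-dimensional refinement to
#' tolerance 1e-6; a flat likelihood (e.g. identity kinship) resolves to
#' the smallest h2 attaining the maximum.
#'
#' @param y numeric trait vector, complete (no missing values; see
#'   [meanImpute()]).
#' @param XL n x (p-1) covariate matrix including the intercept column.
#' @param ek the [EigenKinship-class] of the study kinship.
#' @param reml use the restricted likelihood (default maximum likelihood).
#' @param traitId optional identifier stored in the result.
#' @return A [VarianceEstimate-class]; `nIterations()` reports the total
#'   number of likelihood evaluations (at most 60).
#' @examples
#' set.seed(1)
#' ek <- eigenKinship(diag(40))
#' estimateH2(rnorm(40), matrix(1, 40, 1), ek)
#' @export
estimateH2 <- function(y, XL, ek, reml = FALSE, traitId = character(0)) {
  if (anyNA(y))
    stop("trait has missing values; impute first (see meanImpute)",
         call. = FALSE)
  y <- as.numeric(y)
  if (var(y) == 0) stop("zero-variance trait", call. = FALSE)
  XL <- as.matrix(XL)
  stopifnot(is(ek, "EigenKinship"))
  n <- length(y)
  if (nrow(XL) != n || length(ek@values) != n)
    stop("sample count mismatch between y, XL and the kinship", call. = FALSE)
  V <- ek@vectors
  y_rot <- as.numeric(crossprod(V, y))
  XL_rot <- crossprod(V, XL)
  lam <- ek@values

  evals <- 0L
  obj <- function(h2) {
    evals <<- evals + 1L
    profileLoglik(h2, y_rot, XL_rot, lam, reml = reml)$loglik
  }
  upper <- 1 - 1e-6
  grid <- seq(0, upper, length.out = 21)
  ll <- vapply(grid, obj, numeric(1))
  best <- which(ll >= max(ll) - 1e-9)[1]  # smallest h2 within tolerance

  h2_hat <- grid[best]
  ll_hat <- ll[best]
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  if (hi > lo) {
    opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    ## keep the refined point only if it genuinely improves; ties resolve
    ## to the smaller h2 from the grid
    if (opt$objective > ll_hat + 1e-9) {
      h2_hat <- opt$maximum
      ll_hat <- opt$objective
    }
  }
  final <- profileLoglik(h2_hat, y_rot, XL_rot, lam, reml = reml)
  evals <- evals + 1L
  new("VarianceEstimate", sigma2 = final$sigma2, h2 = h2_hat,
      nIter = evals, logLik = final$loglik,
      traitId = as.character(traitId))
}
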