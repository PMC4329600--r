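#' Build the mixed-model trait covariance matrix
#'
#' Forms \eqn{M = \sigma^2 (h^2 \Phi + (1 - h^2) I)}: the covariance of a
#' trait whose polygenic component (variance fraction h^2) is structured by
#' the kinship matrix and whose residual (fraction 1 - h^2) is independent
#' across samples.
#'
#' @param phi a [KinshipMatrix-class] or a square numeric matrix.
#' @param sigma2 total trait variance, > 0.
#' @param h2 heritability coefficient in `[0, 1)`.
#'
#' @return n x n symmetric covariance matrix, positive definite whenever
#'   `phi` is positive semidefinite.
#' @examples
#' buildCovariance(diag(2), sigma2 = 2, h2 = 0.5)
#' @export
buildCovariance <- function(phi, sigma2, h2) {
  v <- if (is(phi, "KinshipMatrix")) phi@values else phi
  .checkMatrix(v, "phi")
  if (nrow(v) != ncol(v)) stop("'phi' must be square", call. = FALSE)
  .checkScalar(sigma2, "sigma2", lower = 0, open_lower = TRUE)
  .checkScalar(h2, "h2", lower = 0, upper = 1, open_upper = TRUE)
  M <- sigma2 * (h2 * v + (1 - h2) * diag(nrow(v)))
  (M + t(M)) / 2
}

#' Generalized least squares by Cholesky whitening
#'
#' Reference solver for the per-cell association problem
#' \eqn{b = (X' M^{-1} X)^{-1} X' M^{-1} y}. The covariance is factored
#' (never inverted): with \eqn{L L' = M}, the model is whitened to ordinary
#' least squares and solved by QR with column-pivot rank detection.
#'
#' The coefficient covariance is reported as \eqn{(X' M^{-1} X)^{-1}} with
#' no further rescaling, the convention of the two-step scan where `M`
#' already carries the step-one variance estimate. Set `rescale = TRUE` to
#' multiply it by the whitened residual mean square `RSS / (n - p)` instead.
#'
#' @param X n x p design matrix of full column rank.
#' @param y numeric response vector of length n.
#' @param M n x n positive-definite covariance matrix (e.g. from
#'   [buildCovariance()]).
#' @param rescale rescale the coefficient covariance by the residual mean
#'   square (default `FALSE`).
#'
#' @return A list with `beta` (length-p estimates), `se` (standard errors),
#'   and `cov` (p x p coefficient covariance, symmetric positive definite).
#' @examples
#' X <- cbind(1, c(-1, 0, 1))
#' glsSolve(X, c(1, 2, 4), diag(3))$beta
#' @export
glsSolve <- function(X, y, M, rescale = FALSE) {
  X <- as.matrix(X)
  .checkMatrix(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length of 'y' must equal nrow(X)", call. = FALSE)
  if (!all(dim(M) == c(n, n)))
    stop("'M' must be an n x n matrix", call. = FALSE)
  L <- cholCovariance(M)
  Xw <- whitenMatrix(L, X)
  yw <- whitenMatrix(L, y)
  .whitenedLS(Xw, yw, rescale = rescale,
              colnames = colnames(X) %||% paste0("x", seq_len(p)))
}

## OLS on whitened data via pivoted QR; shared by glsSolve and wlsSolve.
.whitenedLS <- function(Xw, yw, rescale = FALSE, colnames = NULL) {
  n <- nrow(Xw); p <- ncol(Xw)
  colnames <- colnames %||% paste0("x", seq_len(p))
  tol <- 1e-10
  qx <- qr(Xw, tol = tol)
  if (qx$rank < p) {
    bad <- qx$pivot[(qx$rank + 1L):p]
    stop(sprintf("design matrix is rank deficient: column%s %s collinear",
                 if (length(bad) > 1) "s" else "",
                 paste(sQuote(colnames[bad]), collapse = ", ")),
         call. = FALSE)
  }
  beta <- qr.coef(qx, yw)
  R <- qr.R(qx)
  covp <- chol2inv(R)
  piv <- qx$pivot
  cov <- matrix(0, p, p)
  cov[piv, piv] <- covp
  if (rescale) {
    rss <- sum((yw - Xw %*% beta)^2)
    cov <- cov * rss / (n - p)
  }
  cov <- (cov + t(cov)) / 2
  se <- sqrt(diag(cov))
  names(beta) <- names(se) <- colnames
  dimnames(cov) <- list(colnames, colnames)
  list(beta = as.numeric(beta), se = as.numeric(se), cov = cov)
}

#' Wald test for a single coefficient
#'
#' Two-sided Wald test: `chi2 = (beta / se)^2` referred to the chi-squared
#' distribution with one degree of freedom.
#'
#' @param beta coefficient estimate.
#' @param se its standard error, > 0.
#' @return A list with `chi2` and `pvalue`.
#' @examples
#' waldTest(1.96, 1)$pvalue  # ~ 0.05
#' @export
waldTest <- function(beta, se) {
  if (!is.numeric(se) || any(!is.finite(se)) || any(se <= 0))
    stop("'se' must be positive and finite; degenerate test", call. = FALSE)
  chi2 <- (beta / se)^2
  list(chi2 = chi2, pvalue = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genomic-control inflation factor
#'
#' The median of the observed association chi-squared statistics divided by
#' the median of the null chi-squared distribution with one degree of
#' freedom (about 0.4549). Values near 1 indicate calibrated tests; values
#' above 1 indicate inflation from uncorrected structure.
#'
#' @param chi2_values non-empty vector of non-negative Wald statistics.
#' @return The inflation factor lambda (positive scalar).
#' @examples
#' gcLambda(qchisq(0.5, 1))  # exactly 1
#' @export
gcLambda <- function(chi2_values) {
  if (length(chi2_values) == 0)
    stop("'chi2_values' must be non-empty", call. = FALSE)
  if (any(!is.finite(chi2_values)) || any(chi2_values < 0))
    stop("'chi2_values' must be finite and non-negative", call. = FALSE)
  median(chi2_values) / qchisq(0.5, df = 1)
}

#' Bonferroni-adjusted significance threshold
#'
#' Divides the per-test significance level by the number of tests. With the
#' conventional genome-wide level 5e-8 and 107,144 traits this gives the
#' multi-trait threshold 4.7e-13 (two significant figures).
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_tests number of tests, >= 1.
#' @return The per-test threshold `alpha / n_tests`.
#' @examples
#' signif(bonferroniThreshold(5e-8, 107144), 2)
#' @export
bonferroniThreshold <- function(alpha, n_tests) {
  .checkScalar(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1 ||
      n_tests != floor(n_tests))
    stop("'n_tests' must be a positive integer", call. = FALSE)
  alpha / n_tests
}
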