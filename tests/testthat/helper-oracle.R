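## Independent oracles against which the fast engines are checked.
## These deliberately use the textbook formulas with explicit inverses,
## which the package itself never does.

## GLS estimator b = (X' M^-1 X)^-1 X' M^-1 y with explicit inversion
glsOracle <- function(X, y, M) {
  Minv <- solve(M)
  XtMi <- t(X) %*% Minv
  cov <- solve(XtMi %*% X)
  beta <- cov %*% (XtMi %*% y)
  list(beta = as.numeric(beta), se = sqrt(diag(cov)),
       cov = (cov + t(cov)) / 2)
}

## dense multivariate-normal log-likelihood of y ~ N(X beta, M)
denseLoglik <- function(y, X, beta, M) {
  n <- length(y)
  r <- y - as.numeric(X %*% beta)
  ld <- determinant(M, logarithm = TRUE)$modulus[1]
  -0.5 * (n * log(2 * pi) + ld + sum(r * solve(M, r)))
}

## random symmetric positive-definite matrix with unit-scale diagonal
randomPSD <- function(n) {
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) / n + diag(n) * 0.5
  (S + t(S)) / 2
}

## random full-rank design with an intercept column
randomDesign <- function(n, p) {
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("intercept", if (p > 1) paste0("x", seq_len(p - 1)))
  X
}

relDiff <- function(a, b) {
  denom <- pmax(abs(a), abs(b), 1e-12)
  max(abs(a - b) / denom)
}
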