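## Synthetic-data generator: kinships with family-block structure,
## independent-site genotypes, and mixed-model phenotypes with known
## ground truth. Every stochastic component draws from its own stream
## derived from the master seed, so adding traits never perturbs the
## genotypes.

#' Study conditions for the synthetic-data generator
#'
#' Constructs a validated [SimConfig-class]. Defaults describe a
#' family-structured cohort of moderate size: 500 samples in full-sib
#' families of five, 1000 independent SNPs with minor allele frequencies
#' uniform on (0.05, 0.5), one trait with heritability 0.5 and unit total
#' variance, an intercept plus one standard-normal covariate with null
#' effects, and no causal SNPs.
#'
#' @param n,m,t sample, SNP and trait counts.
#' @param p total fixed effects per SNP model (covariates incl. intercept,
#'   plus the SNP); `p = 2` means intercept + SNP... note the covariate
#'   block has `p - 1` columns of which the first is the intercept.
#' @param familySize full-sib family block size of the kinship (1 =
#'   unrelated).
#' @param h2,sigma2 true per-trait heritability and total variance
#'   (recycled to `t`).
#' @param causal,gamma causal SNP indices and their effect sizes.
#' @param betaL covariate fixed effects (length `p - 1`, default zeros).
#' @param mafRange per-SNP allele-frequency range.
#' @param seed master seed.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(n = 100, m = 50, seed = 7)
#' @export
simConfig <- function(n = 500, m = 1000, t = 1, p = 2, familySize = 5,
                      h2 = 0.5, sigma2 = 1, causal = integer(0),
                      gamma = numeric(0), betaL = NULL,
                      mafRange = c(0.05, 0.5), seed = 1) {
  new("SimConfig", n = as.integer(n), m = as.integer(m), t = as.integer(t),
      p = as.integer(p), familySize = as.integer(familySize),
      h2 = rep_len(as.numeric(h2), t), sigma2 = rep_len(as.numeric(sigma2), t),
      causal = as.integer(causal), gamma = as.numeric(gamma),
      betaL = if (is.null(betaL)) numeric(p - 1) else as.numeric(betaL),
      mafRange = as.numeric(mafRange), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: n = %d, m = %d, t = %d, p = %d (family size %d, seed %d)\n",
              object@n, object@m, object@t, object@p, object@familySize,
              object@seed))
  cat(sprintf("  h2 in [%.3g, %.3g]; %d causal SNP(s)\n",
              min(object@h2), max(object@h2), length(object@causal)))
})

#' Simulate a family-block kinship matrix
#'
#' Block-diagonal relationship matrix: samples are grouped into full-sib
#' families of `familySize` with relationship coefficient 0.5 within a
#' family and 1 on the diagonal (a remainder forms a smaller final
#' family). The result is positive definite by construction, so its
#' spectrum never needs clipping.
#'
#' @param config a [SimConfig-class] (only `n` and `familySize` are used).
#' @return A [KinshipMatrix-class].
#' @examples
#' simulateKinship(simConfig(n = 4, familySize = 2))
#' @export
simulateKinship <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n
  fs <- config@familySize
  phi <- diag(n) * 0.5
  starts <- seq(1L, n, by = fs)
  for (s in starts) {
    idx <- s:min(s + fs - 1L, n)
    phi[idx, idx] <- phi[idx, idx] + 0.5
  }
  kinshipMatrix(phi, paste0("S", seq_len(n)), checkPSD = FALSE)
}

#' Simulate independent-site genotype dosages
#'
#' Per SNP an allele frequency is drawn uniformly from `mafRange` and
#' dosages are binomial(2, f) independently across samples and sites.
#' Relatedness enters the generative model only through the kinship used
#' for the polygenic effect; the two-step method requires no linkage
#' disequilibrium.
#'
#' @param config a [SimConfig-class].
#' @return n x m dosage matrix with row ids `S*` and column ids `snp*`.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n; m <- config@m
  set.seed(.componentSeed(config@seed, "genotypes"))
  f <- runif(m, config@mafRange[1], config@mafRange[2])
  G <- vapply(seq_len(m), function(j) rbinom(n, 2L, f[j]), numeric(n))
  dimnames(G) <- list(paste0("S", seq_len(n)), paste0("snp", seq_len(m)))
  G
}

#' Simulate covariates
#'
#' Intercept column plus `p - 2` standard-normal covariates, drawn from
#' the covariate stream of the master seed.
#'
#' @param config a [SimConfig-class].
#' @return n x (p - 1) covariate matrix, intercept first.
#' @export
simulateCovariates <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n; q <- config@p - 1L
  set.seed(.componentSeed(config@seed, "covariates"))
  XL <- cbind(intercept = rep(1, n))
  if (q > 1L) {
    Z <- matrix(rnorm(n * (q - 1L)), n, q - 1L)
    colnames(Z) <- paste0("cov", seq_len(q - 1L))
    XL <- cbind(XL, Z)
  }
  rownames(XL) <- paste0("S", seq_len(n))
  XL
}

#' Simulate mixed-model phenotypes with known ground truth
#'
#' Per trait j draws
#' \deqn{y = X_L \beta_L + \sum_c x_c \gamma_c + g + e,\quad
#'       g \sim N(0, \sigma_j^2 h_j^2 \Phi),\
#'       e \sim N(0, \sigma_j^2 (1 - h_j^2) I).}
#' Each trait has its own random stream derived from the master seed, so
#' the same seed reproduces the matrix bit for bit and extending `t` does
#' not change existing traits.
#'
#' @param config a [SimConfig-class].
#' @param phi the [KinshipMatrix-class] structuring the polygenic effect.
#' @param genotypes n x m dosage matrix (used for the causal effects).
#' @param XL covariate matrix from [simulateCovariates()]; regenerated
#'   from `config` when omitted.
#' @return n x t phenotype matrix.
#' @export
simulatePhenotypes <- function(config, phi, genotypes, XL = NULL) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n
  phiV <- if (is(phi, "KinshipMatrix")) phi@values else as.matrix(phi)
  if (!all(dim(phiV) == c(n, n)))
    stop("kinship dimension does not match config n", call. = FALSE)
  if (is.null(XL)) XL <- simulateCovariates(config)
  fixed <- as.numeric(XL %*% config@betaL)
  if (length(config@causal)) {
    G <- as.matrix(genotypes)
    fixed <- fixed +
      as.numeric(G[, config@causal, drop = FALSE] %*% config@gamma)
  }
  ## Cholesky of phi for the polygenic draw; family-block kinships are PD,
  ## near-PSD empirical ones get a tiny ridge
  Lphi <- tryCatch(t(chol(phiV)),
                   error = function(e) t(chol(phiV + 1e-8 * diag(n))))
  Y <- matrix(NA_real_, n, config@t)
  for (j in seq_len(config@t)) {
    h2 <- config@h2[j]; s2 <- config@sigma2[j]
    set.seed(.componentSeed(config@seed, paste0("trait:", j)))
    g <- sqrt(s2 * h2) * as.numeric(Lphi %*% rnorm(n))
    e <- sqrt(s2 * (1 - h2)) * rnorm(n)
    Y[, j] <- fixed + g + e
  }
  dimnames(Y) <- list(paste0("S", seq_len(n)), paste0("trait", seq_len(config@t)))
  Y
}

#' Simulate a complete study
#'
#' Convenience wrapper drawing kinship, genotypes, covariates and
#' phenotypes from one [SimConfig-class].
#'
#' @param config a [SimConfig-class].
#' @return List with `phi`, `genotypes`, `XL`, `phenotypes` and `config`.
#' @examples
#' dat <- simulateDataset(simConfig(n = 60, m = 20, seed = 3))
#' dim(dat$genotypes)
#' @export
simulateDataset <- function(config) {
  phi <- simulateKinship(config)
  G <- simulateGenotypes(config)
  XL <- simulateCovariates(config)
  Y <- simulatePhenotypes(config, phi, G, XL)
  list(phi = phi, genotypes = G, XL = XL, phenotypes = Y, config = config)
}

#' Expand base traits into all pairwise ratio traits
#'
#' Metabolomics-style trait expansion: the k base columns are kept and all
#' k(k-1) ordered pairwise ratios column_i / column_j (i != j) are
#' appended, for k^2 traits in total (328 base measurements give 107,584
#' traits). Base values must be strictly positive.
#'
#' @param base n x k matrix of positive base measurements.
#' @return n x k^2 matrix; ratio columns are labeled `"A/B"`.
#' @examples
#' ncol(ratioTraits(matrix(1:6, 2)))  # 9
#' @export
ratioTraits <- function(base) {
  base <- as.matrix(base)
  k <- ncol(base)
  bad <- which(!(base > 0), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    stop(sprintf("non-positive base value at row %d, column %d; ratios undefined",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  labels <- colnames(base) %||% paste0("T", seq_len(k))
  if (k == 1) {
    colnames(base) <- labels
    return(base)
  }
  out <- matrix(NA_real_, nrow(base), k * k)
  out[, seq_len(k)] <- base
  nm <- character(k * k)
  nm[seq_len(k)] <- labels
  col <- k
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    col <- col + 1L
    out[, col] <- base[, i] / base[, j]
    nm[col] <- paste0(labels[i], "/", labels[j])
  }
  rownames(out) <- rownames(base)
  colnames(out) <- nm
  out
}

#' Replace missing values by the observed mean
#'
#' The simplest imputation adequate for omics assays with a small fraction
#' of missing values: each missing entry of a vector (or of each matrix
#' column) is replaced by the mean of its observed entries; observed
#' entries are untouched.
#'
#' @param y numeric vector or matrix with possible `NA`s.
#' @return The completed vector or matrix.
#' @examples
#' meanImpute(c(2, NA, 4))  # 2 3 4
#' @export
meanImpute <- function(y) {
  if (is.matrix(y)) {
    for (j in seq_len(ncol(y))) y[, j] <- meanImpute(y[, j])
    return(y)
  }
  miss <- is.na(y)
  if (all(miss)) stop("all values missing; nothing to impute from",
                      call. = FALSE)
  if (any(miss)) y[miss] <- mean(y[!miss])
  y
}

#' Genomic relationship matrix from dosages
#'
#' Builds a kinship estimate when no pedigree matrix is available:
#' \eqn{\Phi = Z Z' / m} with `Z` the column-standardized dosage matrix
#' (each SNP centered by its mean and scaled by its standard deviation).
#' Monomorphic columns carry no information and are dropped with a
#' warning.
#'
#' @param genotypes n x m dosage matrix, m >= 2.
#' @return A [KinshipMatrix-class] (symmetric by construction).
#' @export
genomicKinship <- function(genotypes) {
  G <- as.matrix(genotypes)
  .checkMatrix(G, "genotypes")
  mono <- apply(G, 2, function(x) var(x) == 0)
  if (all(mono))
    stop("all genotype columns are monomorphic", call. = FALSE)
  if (any(mono))
    warning(sum(mono), " monomorphic column(s) dropped")
  G <- G[, !mono, drop = FALSE]
  if (ncol(G) < 2)
    stop("need at least 2 polymorphic SNPs", call. = FALSE)
  Z <- scale(G)
  phi <- tcrossprod(Z) / ncol(Z)
  phi <- (phi + t(phi)) / 2
  ids <- make.unique(rownames(G) %||% paste0("S", seq_len(nrow(G))))
  kinshipMatrix(phi, ids, checkPSD = FALSE)
}
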