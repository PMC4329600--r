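#' @import methods
#' @importFrom stats rnorm rbinom runif median optimize pchisq qchisq
#'   pnorm var complete.cases
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame
NULL

#' KinshipMatrix: pairwise genetic relationship coefficients
#'
#' An n x n symmetric positive-semidefinite matrix of relationship
#' coefficients between study samples, together with the sample identifiers
#' in matrix order. This matrix defines the polygenic part of the trait
#' covariance \eqn{M = \sigma^2 (h^2 \Phi + (1-h^2) I)}.
#'
#' @slot values n x n numeric matrix of relationship coefficients.
#' @slot sampleIds character vector of n sample identifiers, in matrix order.
#'
#' @section Validity:
#' The matrix must be square with symmetric entries (to 1e-12 relative),
#' strictly positive diagonal, and ids unique and of matching length. The
#' constructor [kinshipMatrix()] additionally checks (and optionally clips)
#' the spectrum.
#'
#' @seealso [kinshipMatrix()], [eigenKinship()], [simulateKinship()]
#' @export
setClass("KinshipMatrix",
  slots = c(values = "matrix", sampleIds = "character"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("kinship matrix must be square")
  n <- nrow(v)
  if (length(object@sampleIds) != n)
    return("length of sampleIds must equal the matrix dimension")
  if (anyDuplicated(object@sampleIds))
    return("sampleIds must be unique")
  if (anyNA(v)) return("kinship matrix contains missing values")
  scale <- max(abs(v), 1)
  if (max(abs(v - t(v))) > 1e-12 * scale)
    return("kinship matrix is not symmetric to within 1e-12")
  if (any(diag(v) <= 0))
    return("kinship diagonal entries must be strictly positive")
  TRUE
})

#' EigenKinship: the spectral decomposition of a kinship matrix
#'
#' Eigenvalues (descending, clipped below at zero) and orthonormal
#' eigenvectors of a [KinshipMatrix-class], computed once per study and
#' reused by variance-component estimation and the eigen-rotation scan
#' engine.
#'
#' @slot values numeric vector of n eigenvalues in descending order.
#' @slot vectors n x n orthogonal matrix of eigenvectors (columns).
#' @slot sampleIds sample identifiers carried over from the kinship matrix.
#'
#' @seealso [eigenKinship()], [rotateMatrix()], [estimateH2()]
#' @export
setClass("EigenKinship",
  slots = c(values = "numeric", vectors = "matrix", sampleIds = "character"))

setValidity("EigenKinship", function(object) {
  n <- length(object@values)
  if (!all(dim(object@vectors) == c(n, n)))
    return("eigenvector matrix dimensions do not match the eigenvalues")
  if (is.unsorted(rev(object@values)))
    return("eigenvalues must be in descending order")
  if (any(object@values < 0))
    return("eigenvalues must be non-negative after clipping")
  if (length(object@sampleIds) != n)
    return("sampleIds length must equal the matrix dimension")
  TRUE
})

#' VarianceEstimate: per-trait variance components
#'
#' The result of step one of the two-step scan: the maximum-likelihood
#' estimates of the total trait variance sigma^2 and the narrow-sense
#' heritability h^2 under the covariates-only mixed model, defining the
#' trait covariance \eqn{M = \sigma^2 (h^2 \Phi + (1-h^2) I)} that is then
#' held fixed across all SNP tests.
#'
#' @slot sigma2 total trait variance (trait units squared), > 0.
#' @slot h2 heritability coefficient in [0, 1).
#' @slot nIter number of likelihood evaluations spent by the optimizer.
#' @slot logLik maximized profile log-likelihood.
#' @slot traitId identifier of the trait the estimate belongs to.
#'
#' @seealso [estimateH2()], [buildCovariance()]
#' @export
setClass("VarianceEstimate",
  slots = c(sigma2 = "numeric", h2 = "numeric", nIter = "integer",
            logLik = "numeric", traitId = "character"))

setValidity("VarianceEstimate", function(object) {
  if (length(object@sigma2) != 1 || object@sigma2 <= 0)
    return("sigma2 must be a positive scalar")
  if (length(object@h2) != 1 || object@h2 < 0 || object@h2 >= 1)
    return("h2 must lie in [0, 1)")
  if (length(object@nIter) != 1 || object@nIter < 1L)
    return("nIter must be a positive integer")
  TRUE
})

#' SimConfig: study conditions for the synthetic-data generator
#'
#' Captures the dimensions and ground-truth parameters of a simulated
#' mixed-model GWAS: sample size and family structure of the kinship,
#' numbers of SNPs, traits and fixed effects, per-trait heritability and
#' total variance, causal SNPs with their effect sizes, and the master
#' seed from which all component streams are derived.
#'
#' @slot n sample size.
#' @slot m number of SNPs.
#' @slot t number of traits.
#' @slot p total number of fixed effects per SNP model (covariates
#'   including the intercept, plus the SNP itself).
#' @slot familySize size of the full-sib family blocks in the kinship
#'   (remainder samples form a smaller final family); 1 gives unrelated
#'   samples.
#' @slot h2 true heritability per trait (recycled to length t).
#' @slot sigma2 true total variance per trait (recycled to length t).
#' @slot causal integer indices of causal SNPs.
#' @slot gamma effect sizes of the causal SNPs (same length as causal).
#' @slot betaL fixed effects of the covariate block (length p - 1).
#' @slot mafRange range of per-SNP minor allele frequencies.
#' @slot seed master seed; every component stream is derived from it.
#'
#' @seealso [simConfig()], [simulateDataset()]
#' @export
setClass("SimConfig",
  slots = c(n = "integer", m = "integer", t = "integer", p = "integer",
            familySize = "integer", h2 = "numeric", sigma2 = "numeric",
            causal = "integer", gamma = "numeric", betaL = "numeric",
            mafRange = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@n < 2L || object@m < 1L || object@t < 1L || object@p < 2L)
    return("sizes must satisfy n >= 2, m >= 1, t >= 1, p >= 2")
  if (object@familySize < 1L) return("familySize must be >= 1")
  if (any(object@h2 < 0) || any(object@h2 >= 1))
    return("true h2 must lie in [0, 1)")
  if (any(object@sigma2 <= 0)) return("true sigma2 must be positive")
  if (length(object@gamma) != length(object@causal))
    return("gamma must have one effect size per causal SNP")
  if (length(object@causal) &&
      (any(object@causal < 1L) || any(object@causal > object@m)))
    return("causal SNP indices out of range")
  if (length(object@betaL) != object@p - 1L)
    return("betaL must have length p - 1")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || diff(object@mafRange) < 0)
    return("mafRange must be an increasing pair within (0, 0.5]")
  TRUE
})

#' GwasResult: the m x t x p association result cube
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with rows = SNPs and
#' columns = traits. For each fixed-effect coefficient `c` the assays
#' `beta.c` and `se.c` hold the m x t effect estimates and standard errors;
#' assays `chi2` and `pvalue` hold the Wald statistic and two-sided p-value
#' for the SNP coefficient. Together the beta assays form the
#' three-dimensional m x t x p effect cube (see [effectArray()]).
#' Degenerate (e.g. monomorphic) SNP-trait cells carry `NaN` in every assay.
#'
#' @slot coefNames names of the p fixed-effect coefficients, SNP last.
#'
#' @seealso [runCholGwas()], [runEigGwas()], [assocTable()], [writeCube()]
#' @export
setClass("GwasResult",
  contains = "SummarizedExperiment",
  slots = c(coefNames = "character"))

setValidity("GwasResult", function(object) {
  p <- length(object@coefNames)
  if (p < 1) return("coefNames must be non-empty")
  need <- c(paste0("beta.", object@coefNames),
            paste0("se.", object@coefNames), "chi2", "pvalue")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    return(paste("missing assays:", paste(setdiff(need, have), collapse = ", ")))
  TRUE
})
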