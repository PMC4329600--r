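#' Construct a KinshipMatrix
#'
#' Validates symmetry, the diagonal, and (optionally) the spectrum of a
#' relationship matrix and wraps it with its sample identifiers.
#'
#' @param values n x n numeric matrix of relationship coefficients.
#' @param sampleIds character vector of sample ids; defaults to the row
#'   names of `values`, or `S1..Sn` when unnamed.
#' @param checkPSD if `TRUE` (default), verify that the smallest eigenvalue
#'   is no smaller than `-1e-8` times the largest; matrices failing this are
#'   rejected. Mild negative eigenvalues within that band are tolerated here
#'   and clipped later by [eigenKinship()].
#'
#' @return A [KinshipMatrix-class] object.
#' @examples
#' phi <- kinshipMatrix(diag(3))
#' kinshipValues(phi)[1, 1]
#' @export
kinshipMatrix <- function(values, sampleIds = NULL, checkPSD = TRUE) {
  .checkMatrix(values, "values")
  if (is.null(sampleIds))
    sampleIds <- rownames(values) %||% paste0("S", seq_len(nrow(values)))
  obj <- new("KinshipMatrix", values = unname(values),
             sampleIds = as.character(sampleIds))
  if (checkPSD) {
    ev <- eigen(obj@values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
      stop("kinship matrix has eigenvalues well below zero; ",
           "it is not positive semidefinite", call. = FALSE)
  }
  obj
}

#' @describeIn kinshipValues kinship coefficient matrix of a KinshipMatrix
#' @export
setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)

#' @describeIn sampleIds sample ids of a KinshipMatrix
#' @export
setMethod("sampleIds", "KinshipMatrix", function(x) x@sampleIds)

#' @describeIn sampleIds sample ids of an EigenKinship
#' @export
setMethod("sampleIds", "EigenKinship", function(x) x@sampleIds)

#' Accessors for KinshipMatrix
#' @name kinshipValues
#' @param x a [KinshipMatrix-class].
#' @return `kinshipValues()` returns the n x n coefficient matrix.
NULL

#' Sample identifiers
#' @name sampleIds
#' @param x a [KinshipMatrix-class] or [EigenKinship-class].
#' @return Character vector of sample ids in matrix order.
NULL

setMethod("dim", "KinshipMatrix", function(x) dim(x@values))

setMethod("show", "KinshipMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("KinshipMatrix with %d samples\n", n))
  cat(sprintf("  mean diagonal: %.4f; mean off-diagonal: %.4f\n",
              mean(diag(object@values)),
              if (n > 1) mean(object@values[upper.tri(object@values)]) else NA))
})

#' Accessors for EigenKinship
#' @name eigenKinship-accessors
#' @param x an [EigenKinship-class].
#' @return `eigenValues()` the descending eigenvalues; `eigenVectors()` the
#'   orthogonal eigenvector matrix.
NULL

#' @describeIn eigenKinship-accessors eigenvalues, descending
#' @export
setMethod("eigenValues", "EigenKinship", function(x) x@values)

#' @describeIn eigenKinship-accessors eigenvector matrix
#' @export
setMethod("eigenVectors", "EigenKinship", function(x) x@vectors)

setMethod("show", "EigenKinship", function(object) {
  n <- length(object@values)
  cat(sprintf("EigenKinship for %d samples\n", n))
  cat(sprintf("  eigenvalue range: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

#' Accessors for VarianceEstimate
#' @name varianceEstimate-accessors
#' @param x a [VarianceEstimate-class].
#' @param object a [VarianceEstimate-class] (for `logLik`).
#' @param ... unused.
#' @return `sigma2()` the total variance; `heritability()` the h^2 estimate;
#'   `nIterations()` the likelihood-evaluation count; `logLik()` the
#'   maximized log-likelihood.
NULL

#' @describeIn varianceEstimate-accessors total trait variance
#' @export
setMethod("sigma2", "VarianceEstimate", function(x) x@sigma2)

#' @describeIn varianceEstimate-accessors heritability estimate
#' @export
setMethod("heritability", "VarianceEstimate", function(x) x@h2)

#' @describeIn varianceEstimate-accessors likelihood evaluations used
#' @export
setMethod("nIterations", "VarianceEstimate", function(x) x@nIter)

#' @describeIn varianceEstimate-accessors maximized log-likelihood
#' @export
setMethod("logLik", "VarianceEstimate", function(object, ...) object@logLik)

setMethod("show", "VarianceEstimate", function(object) {
  cat(sprintf("VarianceEstimate%s: sigma2 = %.6g, h2 = %.6g (logLik %.6g, %d evals)\n",
              if (length(object@traitId)) paste0(" [", object@traitId, "]") else "",
              object@sigma2, object@h2, object@logLik, object@nIter))
})

## ---- GwasResult ----

#' Accessors for GwasResult
#'
#' @name gwasResult-accessors
#' @param x a [GwasResult-class].
#' @return `effectArray()` and `seArray()` return the m x t x p arrays of
#'   effects and standard errors; `chiSquared()` and `pValues()` the m x t
#'   Wald statistics and p-values for the SNP coefficient; `snpIds()`,
#'   `traitIds()` and `coefNames()` the axis labels.
NULL

#' @describeIn gwasResult-accessors m x t x p array of effect estimates
#' @export
setMethod("effectArray", "GwasResult", function(x) {
  .stackAssays(x, "beta.")
})

#' @describeIn gwasResult-accessors m x t x p array of standard errors
#' @export
setMethod("seArray", "GwasResult", function(x) {
  .stackAssays(x, "se.")
})

.stackAssays <- function(x, prefix) {
  p <- length(x@coefNames)
  a <- array(NA_real_, dim = c(nrow(x), ncol(x), p),
             dimnames = list(rownames(x), colnames(x), x@coefNames))
  for (k in seq_len(p))
    a[, , k] <- SummarizedExperiment::assay(x, paste0(prefix, x@coefNames[k]))
  a
}

#' @describeIn gwasResult-accessors Wald chi-squared for the SNP coefficient
#' @export
setMethod("chiSquared", "GwasResult", function(x)
  SummarizedExperiment::assay(x, "chi2"))

#' @describeIn gwasResult-accessors two-sided p-values for the SNP coefficient
#' @export
setMethod("pValues", "GwasResult", function(x)
  SummarizedExperiment::assay(x, "pvalue"))

#' @describeIn gwasResult-accessors SNP identifiers (rows)
#' @export
setMethod("snpIds", "GwasResult", function(x) rownames(x))

#' @describeIn gwasResult-accessors trait identifiers (columns)
#' @export
setMethod("traitIds", "GwasResult", function(x) colnames(x))

#' @describeIn gwasResult-accessors coefficient names, SNP last
#' @export
setMethod("coefNames", "GwasResult", function(x) x@coefNames)

setMethod("show", "GwasResult", function(object) {
  cat(sprintf("GwasResult: %d SNPs x %d traits x %d coefficients\n",
              nrow(object), ncol(object), length(object@coefNames)))
  pv <- SummarizedExperiment::assay(object, "pvalue")
  ok <- is.finite(pv)
  if (any(ok)) {
    i <- which(pv == min(pv[ok]), arr.ind = TRUE)[1, ]
    cat(sprintf("  top hit: %s / %s, p = %.4g\n",
                rownames(object)[i[1]], colnames(object)[i[2]],
                min(pv[ok])))
  }
  if (any(!ok))
    cat(sprintf("  degenerate cells: %d\n", sum(!ok)))
})

#' Long-format association table
#'
#' Flattens a [GwasResult-class] into one row per (SNP, trait, coefficient)
#' with effect, standard error, and the SNP-coefficient Wald statistic and
#' p-value repeated across the coefficients of a cell.
#'
#' @param x a [GwasResult-class].
#' @param ... unused.
#' @return A `data.frame` with columns `snp_id`, `trait_id`, `coefficient`,
#'   `beta`, `se`, `chi2`, `pvalue`.
#' @export
setMethod("assocTable", "GwasResult", function(x, ...) {
  m <- nrow(x); t <- ncol(x); p <- length(x@coefNames)
  B <- effectArray(x); S <- seArray(x)
  data.frame(
    snp_id = rep(rownames(x), times = t * p),
    trait_id = rep(rep(colnames(x), each = m), times = p),
    coefficient = rep(x@coefNames, each = m * t),
    beta = as.vector(B), se = as.vector(S),
    chi2 = rep(as.vector(chiSquared(x)), times = p),
    pvalue = rep(as.vector(pValues(x)), times = p),
    stringsAsFactors = FALSE)
})

## internal: assemble a GwasResult from component matrices
.makeGwasResult <- function(beta, se, chi2, pvalue, snp_ids, trait_ids,
                            coef_names, varianceEstimates = NULL) {
  ## beta, se: list over coefficients of m x t matrices
  assays <- c(
    stats::setNames(beta, paste0("beta.", coef_names)),
    stats::setNames(se, paste0("se.", coef_names)),
    list(chi2 = chi2, pvalue = pvalue))
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(snp_ids, trait_ids); a
  })
  cd <- S4Vectors::DataFrame(row.names = trait_ids)
  if (!is.null(varianceEstimates)) {
    cd$sigma2 <- vapply(varianceEstimates, sigma2, numeric(1))
    cd$h2 <- vapply(varianceEstimates, heritability, numeric(1))
  }
  se_obj <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(row.names = snp_ids),
    colData = cd)
  new("GwasResult", se_obj, coefNames = coef_names)
}
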