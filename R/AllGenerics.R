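#' @rdname kinshipValues
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname eigenKinship-accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname eigenKinship-accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname varianceEstimate-accessors
#' @export
setGeneric("sigma2", function(x) standardGeneric("sigma2"))

#' @rdname varianceEstimate-accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname varianceEstimate-accessors
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("effectArray", function(x) standardGeneric("effectArray"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("seArray", function(x) standardGeneric("seArray"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("chiSquared", function(x) standardGeneric("chiSquared"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))

#' @rdname gwasResult-accessors
#' @export
setGeneric("coefNames", function(x) standardGeneric("coefNames"))

#' @rdname assocTable
#' @export
setGeneric("assocTable", function(x, ...) standardGeneric("assocTable"))
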