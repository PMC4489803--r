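#' @include AllClasses.R
NULL

#' @rdname CallSet-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname CallSet-accessors
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))
#' @rdname CallSet-accessors
#' @export
setGeneric("variantCalls", function(object) standardGeneric("variantCalls"))
#' @rdname CallSet-accessors
#' @export
setGeneric("consensusCalls", function(object) standardGeneric("consensusCalls"))
#' @rdname CallSet-accessors
#' @export
setGeneric("callSets", function(object) standardGeneric("callSets"))
#' @rdname CallSet-accessors
#' @export
setGeneric("batchIds", function(object) standardGeneric("batchIds"))

#' @rdname ConcordanceResult-accessors
#' @export
setGeneric("concordanceRate", function(object) standardGeneric("concordanceRate"))
#' @rdname ConcordanceResult-accessors
#' @export
setGeneric("nConcordant", function(object) standardGeneric("nConcordant"))
#' @rdname ConcordanceResult-accessors
#' @export
setGeneric("pairResults", function(object) standardGeneric("pairResults"))

#' @rdname BinScheme-accessors
#' @export
setGeneric("binLabels", function(object) standardGeneric("binLabels"))
#' @rdname BinScheme-accessors
#' @export
setGeneric("binAssign", function(object, values) standardGeneric("binAssign"))

#' @rdname applyFilter
#' @export
setGeneric("applyFilter", function(object, criteria, ...)
  standardGeneric("applyFilter"))
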