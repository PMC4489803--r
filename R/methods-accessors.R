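#' @include AllGenerics.R
NULL

#' Accessors for CallSet and ReplicateSet objects
#'
#' @param object a [CallSet-class] or [ReplicateSet-class].
#' @return \code{sampleId}, \code{replicateId}: character(1).
#'   \code{variantCalls}, \code{consensusCalls}: the underlying data.frame
#'   (\code{consensusCalls} may be NULL). \code{callSets}: list of CallSet.
#'   \code{batchIds}: character vector of batch identifiers.
#' @name CallSet-accessors
NULL

#' @rdname CallSet-accessors
#' @export
setMethod("sampleId", "CallSet", function(object) object@sampleId)
#' @rdname CallSet-accessors
#' @export
setMethod("sampleId", "ReplicateSet", function(object) object@sampleId)
#' @rdname CallSet-accessors
#' @export
setMethod("replicateId", "CallSet", function(object) object@replicateId)
#' @rdname CallSet-accessors
#' @export
setMethod("variantCalls", "CallSet", function(object) object@variants)
#' @rdname CallSet-accessors
#' @export
setMethod("consensusCalls", "CallSet", function(object) object@consensus)
#' @rdname CallSet-accessors
#' @export
setMethod("callSets", "ReplicateSet", function(object) object@callSets)
#' @rdname CallSet-accessors
#' @export
setMethod("batchIds", "ReplicateSet", function(object) object@batchIds)

#' Accessors for ConcordanceResult objects
#'
#' @param object a [ConcordanceResult-class].
#' @return \code{concordanceRate}: the rate Rc in [0, 1]. \code{nConcordant}:
#'   the concordant count Nc. \code{pairResults}: per-pair results (empty
#'   unless the object summarises a triplicate).
#' @name ConcordanceResult-accessors
NULL

#' @rdname ConcordanceResult-accessors
#' @export
setMethod("concordanceRate", "ConcordanceResult", function(object) object@rate)
#' @rdname ConcordanceResult-accessors
#' @export
setMethod("nConcordant", "ConcordanceResult", function(object) object@nConcordant)
#' @rdname ConcordanceResult-accessors
#' @export
setMethod("pairResults", "ConcordanceResult", function(object) object@pairResults)

#' Accessors for BinScheme objects
#'
#' \code{binAssign} maps factor values to bin labels: numeric schemes
#' transform the values (if the scheme says so), then place them in
#' left-closed, right-open intervals, the final bin closed above; values
#' outside the edge range or NA map to NA. Categorical schemes match values
#' against the label set.
#'
#' @param object a [BinScheme-class].
#' @param values vector of factor values to assign.
#' @return \code{binLabels}: character vector of bin labels.
#'   \code{binAssign}: factor of bin labels (levels = scheme labels), NA for
#'   out-of-range values.
#' @name BinScheme-accessors
NULL

#' @rdname BinScheme-accessors
#' @export
setMethod("binLabels", "BinScheme", function(object) object@labels)

#' @rdname BinScheme-accessors
#' @export
setMethod("binAssign", "BinScheme", function(object, values) {
  if (object@type == "categorical") {
    return(factor(as.character(values), levels = object@labels))
  }
  x <- as.numeric(values)
  if (object@transform == "log10") {
    x[!is.na(x) & x <= 0] <- NA_real_
    x <- log10(x)
  }
  e <- object@edges
  idx <- findInterval(x, e, rightmost.closed = TRUE, left.open = FALSE)
  idx[!is.na(idx) & (idx < 1L | idx > length(e) - 1L)] <- NA_integer_
  factor(object@labels[idx], levels = object@labels)
})

setMethod("show", "CallSet", function(object) {
  cat("CallSet:", object@sampleId, "/", object@replicateId, "\n")
  cat("  variants: ", nrow(object@variants), " SNV calls\n", sep = "")
  if (is.null(object@consensus)) {
    cat("  consensus: <none>\n")
  } else {
    nN <- sum(object@consensus$call == "N", na.rm = TRUE)
    cat("  consensus: ", nrow(object@consensus), " positions (",
        nN, " ambiguous N)\n", sep = "")
  }
})

setMethod("show", "ReplicateSet", function(object) {
  cat("ReplicateSet:", object@sampleId,
      sprintf("(%d replicates; batches: %s)\n", length(object@callSets),
              paste(object@batchIds, collapse = ", ")))
  for (cs in object@callSets)
    cat(sprintf("  %s: %d SNV calls\n", cs@replicateId, nrow(cs@variants)))
})

setMethod("show", "ConcordanceResult", function(object) {
  if (length(object@pairResults)) {
    cat(sprintf("ConcordanceResult (mean of %d pairs): Rc = %.4f\n",
                length(object@pairResults), object@rate))
    for (p in object@pairResults)
      cat(sprintf("  pair: Nc=%g N1=%g N2=%g Rc=%.4f\n",
                  p@nConcordant, p@nTotal1, p@nTotal2, p@rate))
  } else {
    cat(sprintf("ConcordanceResult: Nc=%g N1=%g N2=%g Rc=%.4f\n",
                object@nConcordant, object@nTotal1, object@nTotal2,
                object@rate))
  }
})

setMethod("show", "BinScheme", function(object) {
  cat("BinScheme:", object@factorName,
      sprintf("(%s, %d bins%s)\n", object@type, length(object@labels),
              if (object@transform == "log10") ", log10 scale" else ""))
  cat(" ", paste(object@labels, collapse = " | "), "\n")
})

setMethod("show", "FilterCriteria", function(object) {
  cat(sprintf(
    "FilterCriteria: coverage>=%g vac>=%g vaf>=%g vaq>=%g%s\n",
    object@minCoverage, object@minVac, object@minVaf, object@minVaq,
    if (is.na(object@maxPvalue)) "" else sprintf(" p<=%g", object@maxPvalue)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d bp, %d true variants, %d replicates, seed %d\n",
    object@nTargetBp, object@nTrueVariants, object@nReplicates, object@seed))
})
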