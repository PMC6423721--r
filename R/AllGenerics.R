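#' Accessors for psnet S4 classes
#'
#' Small accessor generics: `layerName`, `patientIDs`, `variableIDs` and
#' `layerValues` for [PatientLayer-class]; `featureName`, `metricName`,
#' `networkNodes` and `networkEdges` for [SimilarityNetwork-class];
#' `geneSets` and `setDescriptions` for [GeneSetList-class].
#'
#' @param x object to access.
#' @return The corresponding slot content (see details per class).
#' @name psnet-accessors
NULL

#' @rdname psnet-accessors
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))
#' @rdname psnet-accessors
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))
#' @rdname psnet-accessors
#' @export
setGeneric("variableIDs", function(x) standardGeneric("variableIDs"))
#' @rdname psnet-accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))
#' @rdname psnet-accessors
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))
#' @rdname psnet-accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))
#' @rdname psnet-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname psnet-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname psnet-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname psnet-accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname psnet-accessors
setMethod("layerName", "PatientLayer", function(x) x@layerName)
#' @rdname psnet-accessors
setMethod("patientIDs", "PatientLayer", function(x) rownames(x@values))
#' @rdname psnet-accessors
setMethod("variableIDs", "PatientLayer", function(x) colnames(x@values))
#' @rdname psnet-accessors
setMethod("layerValues", "PatientLayer", function(x) x@values)
#' @rdname psnet-accessors
setMethod("featureName", "SimilarityNetwork", function(x) x@featureName)
#' @rdname psnet-accessors
setMethod("metricName", "SimilarityNetwork", function(x) x@metricName)
#' @rdname psnet-accessors
setMethod("networkNodes", "SimilarityNetwork", function(x) x@nodes)
#' @rdname psnet-accessors
setMethod("networkEdges", "SimilarityNetwork", function(x) x@edges)
#' @rdname psnet-accessors
setMethod("geneSets", "GeneSetList", function(x) x@sets)
#' @rdname psnet-accessors
setMethod("setDescriptions", "GeneSetList", function(x) {
  d <- x@descriptions
  names(d) <- names(x@sets)
  d
})

setMethod("show", "PatientLayer", function(object) {
  v <- object@values
  cat(sprintf("PatientLayer '%s': %d patients x %d variables (%d missing)\n",
              object@layerName, nrow(v), ncol(v), sum(is.na(v))))
})

setMethod("show", "SimilarityNetwork", function(object) {
  e <- object@edges
  rng <- if (nrow(e)) sprintf("[%.3g, %.3g]", min(e$weight), max(e$weight))
         else "(none)"
  cat(sprintf(
    "SimilarityNetwork '%s' (metric %s): %d nodes, %d edges, weights %s\n",
    object@featureName, object@metricName, length(object@nodes), nrow(e), rng))
})

setMethod("show", "GeneSetList", function(object) {
  sz <- vapply(object@sets, length, 1L)
  cat(sprintf("GeneSetList: %d sets, sizes %d-%d\n",
              length(sz), if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L))
})

#' Number of patients/nodes
#'
#' @param x a [PatientLayer-class] or [SimilarityNetwork-class].
#' @return integer count.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))
#' @rdname nPatients
setMethod("nPatients", "PatientLayer", function(x) nrow(x@values))
#' @rdname nPatients
setMethod("nPatients", "SimilarityNetwork", function(x) length(x@nodes))
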