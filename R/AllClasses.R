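#' @import methods
NULL

#' PatientLayer: one data type's patient-by-variable matrix
#'
#' Container for a single data layer (e.g. gene expression, clinical
#' variables): a numeric matrix with patients as rows and variables as
#' columns. Missing entries are permitted and stored as \code{NA}.
#'
#' @slot layerName single string naming the layer.
#' @slot values numeric matrix, patients x variables, with unique rownames
#'   (patient identifiers) and unique colnames (variable identifiers).
#'
#' @seealso [PatientLayer()], [readDataLayer()], [buildDatatypeNetwork()]
#' @exportClass PatientLayer
setClass("PatientLayer",
  representation(layerName = "character", values = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@layerName) != 1L || is.na(object@layerName) ||
        !nzchar(object@layerName))
      msg <- c(msg, "layerName must be a single non-empty string")
    v <- object@values
    if (!is.numeric(v))
      msg <- c(msg, "values must be a numeric matrix")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "patient identifiers (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "variable identifiers (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PatientLayer
#'
#' @param layerName single string naming the layer.
#' @param values numeric matrix (patients x variables) with rownames and
#'   colnames; \code{NA} marks missing entries.
#' @return A [PatientLayer-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("P", 1:3), c("age", "bmi")))
#' PatientLayer("clinical", m)
#' @export
PatientLayer <- function(layerName, values) {
  storage.mode(values) <- "double"
  new("PatientLayer", layerName = layerName, values = values)
}

# metrics whose weights are contractually in [0, 1]
.UNIT_METRICS <- c("normalized", "meanNormalized", "eucscale", "pearscale",
                   "average", "dissimilarity")

#' SimilarityNetwork: a named, weighted, symmetric patient graph
#'
#' One feature's patient similarity network (PSN). Nodes are patients and
#' each undirected edge carries a finite similarity weight. Edges are stored
#' canonically: each unordered pair appears once with endpoints in
#' lexicographic order, rows sorted by endpoints. Self-edges are forbidden.
#' For unit-interval metrics weights must lie in [0, 1]; for
#' \code{"pearson"} in [-1, 1].
#'
#' @slot featureName single string naming the feature this network encodes.
#' @slot metricName single string naming the similarity metric.
#' @slot nodes character vector of unique patient identifiers (includes
#'   patients that currently have no edges).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#'
#' @seealso [SimilarityNetwork()], [sparsifyNetwork()], [combineNetworks()]
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork",
  representation(featureName = "character", metricName = "character",
                 nodes = "character", edges = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@featureName) != 1L)
      msg <- c(msg, "featureName must be a single string")
    if (length(object@metricName) != 1L)
      msg <- c(msg, "metricName must be a single string")
    if (anyDuplicated(object@nodes))
      msg <- c(msg, "node identifiers must be unique")
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% names(e))) {
      msg <- c(msg, "edges must have columns from, to, weight")
      return(msg)
    }
    if (nrow(e)) {
      if (any(e$from >= e$to))
        msg <- c(msg, "edges must satisfy from < to (no self-edges, canonical order)")
      if (!all(c(e$from, e$to) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be listed in nodes")
      if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
        msg <- c(msg, "each unordered pair may appear at most once")
      if (!all(is.finite(e$weight)))
        msg <- c(msg, "edge weights must be finite")
      else {
        if (object@metricName %in% .UNIT_METRICS &&
            (min(e$weight) < 0 || max(e$weight) > 1))
          msg <- c(msg, sprintf("metric '%s' requires weights in [0,1]",
                                object@metricName))
        if (object@metricName == "pearson" &&
            (min(e$weight) < -1 - 1e-12 || max(e$weight) > 1 + 1e-12))
          msg <- c(msg, "pearson weights must lie in [-1,1]")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SimilarityNetwork
#'
#' Canonicalizes the edge list: endpoints of each edge are put in
#' lexicographic order and rows are sorted by (from, to).
#'
#' @param featureName single string naming the feature.
#' @param nodes character vector of patient identifiers; defaults to the
#'   identifiers appearing in \code{edges}.
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}; may have zero rows.
#' @param metricName similarity metric label (e.g. \code{"pearson"},
#'   \code{"normalized"}); \code{"custom"} imposes no weight bounds.
#' @return A [SimilarityNetwork-class] object.
#' @examples
#' e <- data.frame(from = "P2", to = "P1", weight = 0.8)
#' SimilarityNetwork("demo", edges = e, metricName = "normalized")
#' @export
SimilarityNetwork <- function(featureName, nodes = NULL, edges = NULL,
                              metricName = "custom") {
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges)) {
    flip <- edges$from > edges$to
    if (any(flip)) {
      tmp <- edges$from[flip]
      edges$from[flip] <- edges$to[flip]
      edges$to[flip] <- tmp
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$from, edges$to)))
  new("SimilarityNetwork", featureName = featureName,
      metricName = metricName, nodes = as.character(nodes),
      edges = edges[, c("from", "to", "weight")])
}

#' GeneSetList: a named collection of gene sets
#'
#' Gene sets (pathways) as read from a GMT file: a named list of unique
#' member gene symbols plus one description string per set.
#'
#' @slot sets named list of character vectors (de-duplicated, non-empty).
#' @slot descriptions character vector parallel to \code{sets}.
#'
#' @seealso [readGMT()], [buildPathwayNetworks()]
#' @exportClass GeneSetList
setClass("GeneSetList",
  representation(sets = "list", descriptions = "character"),
  validity = function(object) {
    msg <- character(0)
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set names must be present and unique")
    if (any(!vapply(object@sets, length, 1L)))
      msg <- c(msg, "member lists must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 1L) > 0))
      msg <- c(msg, "member lists must be de-duplicated")
    if (length(object@descriptions) != length(object@sets))
      msg <- c(msg, "one description per set required")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of gene symbols; members are
#'   de-duplicated, empty sets are dropped with a warning.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A [GeneSetList-class] object.
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  empty <- !vapply(sets, length, 1L)
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
    descriptions <- descriptions[!empty]
  }
  new("GeneSetList", sets = sets,
      descriptions = unname(as.character(descriptions)))
}
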