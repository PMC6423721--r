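#' Read a patient data layer from a tab-delimited file
#'
#' Expects a TSV with a header row of variable names and the patient
#' identifier in the first column. Empty cells and the token \code{"NA"}
#' parse as missing; any other non-numeric cell is an error naming the
#' offending row and column. Row and column order are preserved.
#'
#' @param path path to a tab-delimited file.
#' @param layerName name to give the layer; defaults to the file name
#'   without extension.
#' @return A [PatientLayer-class].
#' @seealso [writeDataLayer()]
#' @export
readDataLayer <- function(path, layerName = NULL) {
  if (is.null(layerName))
    layerName <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("data layer file must have a patient-ID column and >=1 variable")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate patient identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vars <- colnames(tab)[-1L]
  m <- matrix(NA_real_, nrow(tab), length(vars),
              dimnames = list(ids, vars))
  for (j in seq_along(vars)) {
    raw <- trimws(tab[[j + 1L]])
    miss <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop(sprintf(
        "non-numeric value '%s' at patient '%s', variable '%s' in %s",
        raw[bad[1L]], ids[bad[1L]], vars[j], path))
    m[, j] <- num
  }
  PatientLayer(layerName, m)
}

#' Write a patient data layer to a tab-delimited file
#'
#' Inverse of [readDataLayer()]: patient IDs in the first column
#' (\code{"id"}), variables as remaining columns, missing entries written
#' as empty cells.
#'
#' @param layer a [PatientLayer-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDataLayer <- function(layer, path) {
  m <- layerValues(layer)
  out <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a two-column patient label table
#'
#' TSV with header and columns patient ID, class label. Enforces unique
#' patients, at least two classes and at least two members per class.
#'
#' @param path path to the label TSV.
#' @return data.frame with columns \code{id} and \code{label}.
#' @export
readLabelTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("label file must have two columns (id, label)")
  .checkLabels(data.frame(id = tab[[1L]], label = tab[[2L]],
                          stringsAsFactors = FALSE))
}

#' Write a label table
#' @param labels data.frame with columns \code{id}, \code{label}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLabelTable <- function(labels, path) {
  utils::write.table(labels[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' \code{name TAB description TAB member...}. Members are de-duplicated;
#' sets left empty after de-duplication are dropped with a warning; a line
#' with fewer than three fields or a duplicated set name is an error.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetList-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nms
  GeneSetList(sets, desc)
}

#' Write a GeneSetList as GMT
#' @param sets a [GeneSetList-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path) {
  s <- geneSets(sets)
  d <- setDescriptions(sets)
  lines <- vapply(names(s), function(nm)
    paste(c(nm, d[[nm]], s[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a similarity network as a three-column edge list
#'
#' Writes a TSV with header \code{from TAB to TAB weight}; each undirected
#' edge appears once with endpoints in lexicographic order and weights
#' printed to 6 decimal places. An empty network yields a header-only file.
#'
#' @param net a [SimilarityNetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso [readNetwork()], [exportGraphML()]
#' @export
writeNetwork <- function(net, path) {
  e <- networkEdges(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("from\tto\tweight", con)
  if (nrow(e))
    writeLines(sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight), con)
  invisible(path)
}

#' Read a three-column edge-list network
#'
#' @param path path to a TSV written by [writeNetwork()].
#' @param featureName name for the network; defaults to the file name.
#' @param metricName metric label, default \code{"custom"}.
#' @param nodes optional full node set (to preserve isolated patients).
#' @return A [SimilarityNetwork-class].
#' @export
readNetwork <- function(path, featureName = NULL, metricName = "custom",
                        nodes = NULL) {
  if (is.null(featureName))
    featureName <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric"))
  names(tab) <- c("from", "to", "weight")
  SimilarityNetwork(featureName, nodes = nodes, edges = tab,
                    metricName = metricName)
}

#' Export a network to GraphML for external viewers
#'
#' @param net a [SimilarityNetwork-class].
#' @param path output path (.graphml).
#' @param labels optional data.frame(id, label); stored as a node attribute.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(net, path, labels = NULL) {
  g <- .asIgraph(net)
  if (!is.null(labels)) {
    labels <- .checkLabels(labels, minPerClass = 1L)
    igraph::V(g)$class <-
      labels$label[match(igraph::V(g)$name, labels$id)]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# igraph view of a network (weight attribute = stored weight)
.asIgraph <- function(net) {
  e <- networkEdges(net)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = networkNodes(net))
}
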