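#' Integrated network of consistently top-scoring features
#'
#' Combines, by uniform averaging, the networks of features that pass a
#' cross-split consistency criterion; by default the features that attain
#' the maximum possible score in every split. The combination runs over
#' all patients present in the supplied networks.
#'
#' @param scoreTables list of per-split score matrices from
#'   [scoreFeatures()].
#' @param nets named list of [SimilarityNetwork-class] over all patients
#'   (names must cover the selected features).
#' @param criterion either \code{"alwaysMax"} (default: features whose
#'   score equals the round count in every split, any class) or a
#'   character vector of feature names to use directly.
#' @param minFraction passed to [consistencyAcrossSplits()] when
#'   summarizing (only used for the \code{"alwaysMax"} criterion).
#' @return A [SimilarityNetwork-class].
#' @export
integrateTopFeatures <- function(scoreTables, nets,
                                 criterion = "alwaysMax",
                                 minFraction = 0.7) {
  if (is.character(criterion) && length(criterion) == 1L &&
      criterion == "alwaysMax") {
    cons <- consistencyAcrossSplits(scoreTables, minFraction = minFraction)
    feats <- unique(cons$feature[cons$alwaysMax])
  } else {
    feats <- criterion
  }
  feats <- intersect(feats, names(nets))
  if (!length(feats))
    stop("no feature passes the criterion; relax it (e.g. use a score ",
         "threshold instead of the all-splits maximum)")
  combineNetworks(nets[feats], name = "integrated_top")
}

#' Convert a similarity network to a dissimilarity graph
#'
#' Edge-wise involution \eqn{d = 1 - w} for unit-interval similarity
#' weights; absent edges stay absent (they do not become distance 1).
#'
#' @param net a [SimilarityNetwork-class] with weights in [0, 1].
#' @return A [SimilarityNetwork-class] with metric \code{"dissimilarity"}.
#' @export
toDissimilarity <- function(net) {
  e <- networkEdges(net)
  if (nrow(e) && (min(e$weight) < 0 || max(e$weight) > 1))
    stop("similarity weights must lie in [0,1] for dissimilarity conversion")
  e$weight <- 1 - e$weight
  SimilarityNetwork(featureName(net), nodes = networkNodes(net),
                    edges = e, metricName = "dissimilarity")
}

# one-tailed Wilcoxon-Mann-Whitney p for "within collectively smaller than
# between": exact permutation enumeration over midrank sums for small
# samples (handles ties), tie-corrected normal approximation otherwise
.wmwLess <- function(within, between, exactMax = 20L) {
  m <- length(within)
  n <- length(between)
  if (m + n <= exactMax) {
    pooled <- c(within, between)
    r <- rank(pooled)
    obs <- sum(r[seq_len(m)])
    combos <- utils::combn(m + n, m)
    stat <- colSums(matrix(r[combos], nrow = m))
    mean(stat <= obs + 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(within, between,
                                        alternative = "less",
                                        exact = FALSE,
                                        correct = TRUE)$p.value)
  }
}

#' Shortest-path class separation on an integrated network
#'
#' Converts the integrated similarity network to dissimilarity
#' (\eqn{d = 1 - w}), computes weighted shortest paths between all patient
#' pairs with Dijkstra's algorithm, and compares the mean shortest-path
#' distance over unordered same-class pairs with the mean over cross-class
#' pairs. A one-tailed Wilcoxon-Mann-Whitney test asks whether
#' within-class distances are collectively shorter than between-class
#' distances (exact by enumeration when the combined pair count is at most
#' 20, tie-corrected normal approximation otherwise). Unreachable pairs
#' are excluded from the means and counted.
#'
#' @param net a [SimilarityNetwork-class] with weights in [0, 1]
#'   (similarity scale; the dissimilarity conversion happens internally).
#' @param labels data.frame(id, label) covering at least two classes among
#'   the network's nodes.
#' @return list with \code{withinMean}, \code{betweenMean}, \code{pValue},
#'   \code{nWithinPairs}, \code{nBetweenPairs}, \code{nUnreachablePairs}.
#' @export
classSeparation <- function(net, labels) {
  labels <- .checkLabels(labels, minPerClass = 1L)
  dnet <- toDissimilarity(net)
  nodes <- intersect(networkNodes(dnet), labels$id)
  if (length(unique(labels$label[labels$id %in% nodes])) < 2L)
    stop("need at least two classes among the network's nodes")
  g <- .asIgraph(dnet)
  D <- igraph::distances(g, v = nodes, to = nodes,
                         weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  lab <- labels$label[match(nodes, labels$id)]
  same <- outer(lab, lab, "==")
  up <- upper.tri(D)
  within <- D[up & same]
  between <- D[up & !same]
  unreachable <- sum(!is.finite(c(within, between)))
  within <- within[is.finite(within)]
  between <- between[is.finite(between)]
  if (!length(within) || !length(between))
    stop("all pairs unreachable in at least one group")
  list(withinMean = mean(within), betweenMean = mean(between),
       pValue = .wmwLess(within, between),
       nWithinPairs = length(within), nBetweenPairs = length(between),
       nUnreachablePairs = unreachable)
}

#' Export a display-filtered network
#'
#' Two visualization filters: mode \code{"distance"} keeps the shortest
#' \code{fracDistance} of edge distances (i.e. the strongest similarities;
#' \code{floor(frac * E)} edges, ties by weight descending then endpoint
#' IDs); mode \code{"figure"} first drops edges with weight below
#' \code{weightMin} and then keeps the top \code{fracPerNode} of each
#' node's edges (\code{ceiling}, endpoint-union, ties by weight descending
#' then partner ID). Writes a three-column edge list and a node-attribute
#' table (patient, class) next to it.
#'
#' @param net a [SimilarityNetwork-class].
#' @param mode \code{"distance"} or \code{"figure"}.
#' @param path output path for the edge list; the node table is written to
#'   \code{paste0(path, ".nodes")}. \code{NULL} skips writing.
#' @param labels optional data.frame(id, label) for the node table.
#' @param fracDistance fraction of shortest distances kept, default 0.4.
#' @param weightMin minimum weight in figure mode, default 0.7.
#' @param fracPerNode per-node fraction in figure mode, default 0.2.
#' @return the filtered [SimilarityNetwork-class], invisibly.
#' @export
exportDisplayNetwork <- function(net, mode = c("distance", "figure"),
                                 path = NULL, labels = NULL,
                                 fracDistance = 0.4, weightMin = 0.7,
                                 fracPerNode = 0.2) {
  mode <- match.arg(mode)
  e <- networkEdges(net)
  if (mode == "distance") {
    k <- floor(fracDistance * nrow(e))
    ord <- order(-e$weight, e$from, e$to)  # shortest distance = largest weight
    e <- e[sort(ord[seq_len(k)]), , drop = FALSE]
  } else {
    e <- e[e$weight >= weightMin, , drop = FALSE]
    if (nrow(e)) {
      inc <- data.frame(node = c(e$from, e$to), partner = c(e$to, e$from),
                        weight = c(e$weight, e$weight),
                        edge = rep(seq_len(nrow(e)), 2L),
                        stringsAsFactors = FALSE)
      inc <- inc[order(inc$node, -inc$weight, inc$partner), ]
      rk <- stats::ave(seq_len(nrow(inc)), inc$node, FUN = seq_along)
      deg <- table(inc$node)
      keepPer <- ceiling(fracPerNode * as.numeric(deg[inc$node]))
      e <- e[sort(unique(inc$edge[rk <= keepPer])), , drop = FALSE]
    }
  }
  out <- SimilarityNetwork(featureName(net), nodes = networkNodes(net),
                           edges = e, metricName = metricName(net))
  if (!nrow(e)) warning("display filter removed every edge")
  if (!is.null(path)) {
    writeNetwork(out, path)
    nodeTab <- data.frame(id = networkNodes(out),
                          class = if (is.null(labels)) NA_character_
                                  else labels$label[match(networkNodes(out),
                                                          labels$id)],
                          stringsAsFactors = FALSE)
    utils::write.table(nodeTab, paste0(path, ".nodes"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Write a feature score table as TSV
#'
#' One row per (class, feature) pair with the integer resampling score.
#'
#' @param scores matrix from [scoreFeatures()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  long <- data.frame(class = rep(colnames(scores),
                                 each = nrow(scores)),
                     feature = rep(rownames(scores), ncol(scores)),
                     score = as.vector(scores),
                     stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
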