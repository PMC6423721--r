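#' Sparsifier configuration
#'
#' Three knobs control pruning of a similarity network: \code{cutoff}, the
#' minimum edge weight retained; \code{topX}, the number of strongest edges
#' kept per node; and \code{maxEdges}, an optional cap on the total edge
#' count. The conventional defaults for correlation networks are cutoff 0.3
#' and topX 50 with no global cap; exponentially scaled networks use the
#' smallest positive representable weight as cutoff (so only structural
#' pruning applies).
#'
#' @param cutoff minimum retained weight, \code{>= 0}.
#' @param topX maximum retained edges per node, \code{>= 1}.
#' @param maxEdges optional cap on total edges (must be at least the node
#'   count when set, so orphan re-attachment can cover every patient).
#' @return list with class \code{"psnetSparsifierConfig"}.
#' @export
sparsifierConfig <- function(cutoff = 0.3, topX = 50L, maxEdges = NULL) {
  stopifnot(cutoff >= 0, topX >= 1L)
  structure(list(cutoff = cutoff, topX = as.integer(topX),
                 maxEdges = if (is.null(maxEdges)) NULL
                            else as.integer(maxEdges)),
            class = "psnetSparsifierConfig")
}

#' Sparsify a similarity network
#'
#' Applies, in order: (1) remove edges with weight below \code{cutoff};
#' (2) keep an edge iff it is among the \code{topX} strongest edges of
#' either endpoint (ties broken by weight descending, then partner ID
#' ascending); (3) if \code{maxEdges} is set, keep only the globally
#' strongest \code{maxEdges} edges (ties by weight descending, then
#' endpoint IDs); (4) when \code{maxEdges} is set, any patient left
#' edge-free is re-attached through its single strongest edge of the
#' original network, with the weight raised to \code{cutoff} if it falls
#' below it. Step (4) guarantees every patient that had any edge in the
#' input retains at least one, so held-out patients can always be reached
#' by label propagation.
#'
#' The operation is idempotent: sparsifying an already-sparsified network
#' with the same configuration returns it unchanged.
#'
#' @param net a [SimilarityNetwork-class].
#' @param config a [sparsifierConfig()].
#' @return the sparsified [SimilarityNetwork-class] (same nodes).
#' @export
sparsifyNetwork <- function(net, config = sparsifierConfig()) {
  stopifnot(inherits(config, "psnetSparsifierConfig"))
  nodes <- networkNodes(net)
  if (!is.null(config$maxEdges) && config$maxEdges < length(nodes))
    stop("maxEdges must be at least the number of nodes")
  e0 <- networkEdges(net)
  e <- e0[e0$weight >= config$cutoff, , drop = FALSE]

  if (nrow(e)) {
    # per-node rank of incident edges: weight desc, partner ID asc
    inc <- data.frame(node = c(e$from, e$to),
                      partner = c(e$to, e$from),
                      weight = c(e$weight, e$weight),
                      edge = rep(seq_len(nrow(e)), 2L),
                      stringsAsFactors = FALSE)
    inc <- inc[order(inc$node, -inc$weight, inc$partner), ]
    rk <- stats::ave(seq_len(nrow(inc)), inc$node, FUN = seq_along)
    keep <- unique(inc$edge[rk <= config$topX])
    e <- e[sort(keep), , drop = FALSE]
  }

  if (!is.null(config$maxEdges) && nrow(e) > config$maxEdges) {
    ord <- order(-e$weight, e$from, e$to)
    e <- e[sort(ord[seq_len(config$maxEdges)]), , drop = FALSE]
  }

  if (!is.null(config$maxEdges)) {
    covered <- unique(c(e$from, e$to))
    orphanCandidates <- setdiff(unique(c(e0$from, e0$to)), covered)
    if (length(orphanCandidates)) {
      add <- lapply(orphanCandidates, function(p) {
        inc0 <- e0[e0$from == p | e0$to == p, , drop = FALSE]
        partner <- ifelse(inc0$from == p, inc0$to, inc0$from)
        best <- order(-inc0$weight, partner)[1L]
        data.frame(from = inc0$from[best], to = inc0$to[best],
                   weight = max(inc0$weight[best], config$cutoff),
                   stringsAsFactors = FALSE)
      })
      add <- do.call(rbind, add)
      add <- add[!duplicated(paste(add$from, add$to, sep = "\r")), ,
                 drop = FALSE]
      e <- rbind(e, add)
      if (length(msgOrphans <- orphanCandidates))
        message("re-attached ", length(msgOrphans),
                " patient(s) orphaned by sparsification")
    }
  }

  if (!nrow(e))
    message("sparsification of '", featureName(net),
            "' removed every edge")
  SimilarityNetwork(featureName(net), nodes = nodes, edges = e,
                    metricName = metricName(net))
}
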