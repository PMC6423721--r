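#' Feature-selection configuration
#'
#' Controls the resampled query-driven scoring of features: in each of
#' \code{nRounds} rounds a without-replacement subsample of a class's
#' training members is used as the query, every network with a positive
#' fitted weight gains one point, and features reaching
#' \code{selectionThreshold} points are selected for that class.
#'
#' @param nRounds number of resampling rounds R, default 10.
#' @param queryFraction fraction of the class's training members used as
#'   query each round (0 < fraction < 1), default 0.8.
#' @param selectionThreshold integer in 1..R, default 9 (the "at least
#'   9 of 10 resamplings" rule).
#' @param seed master seed for the per-class resampling streams.
#' @param lambda ridge penalty passed to [fitNetworkWeights()].
#' @param includeNonQueryPairs passed to [fitNetworkWeights()];
#'   default FALSE.
#' @return list with class \code{"psnetFSConfig"}.
#' @export
featureSelectionConfig <- function(nRounds = 10L, queryFraction = 0.8,
                                   selectionThreshold = 9L, seed = 42L,
                                   lambda = 1,
                                   includeNonQueryPairs = FALSE) {
  stopifnot(nRounds >= 1L, queryFraction > 0, queryFraction < 1,
            selectionThreshold >= 1L, selectionThreshold <= nRounds,
            lambda > 0)
  structure(list(nRounds = as.integer(nRounds),
                 queryFraction = queryFraction,
                 selectionThreshold = as.integer(selectionThreshold),
                 seed = as.integer(seed), lambda = lambda,
                 includeNonQueryPairs = includeNonQueryPairs),
            class = "psnetFSConfig")
}

#' Draw one query subsample of a class's training members
#'
#' Without-replacement subset of size \code{max(2, round(fraction * n))},
#' drawn from the session RNG stream (seed it for reproducibility);
#' successive calls on one stream yield different subsets.
#'
#' @param ids training patients of one class (at least 3).
#' @param fraction subsample fraction, default 0.8.
#' @return character vector of sampled patient IDs.
#' @export
resampleQuery <- function(ids, fraction = 0.8) {
  n <- length(ids)
  if (n < 3L) stop("class has too few training members to resample (need >= 3)")
  stopifnot(fraction > 0, fraction < 1)
  size <- max(2L, as.integer(round(fraction * n)))
  sample(ids, size)
}

#' Score features by resampled query-driven network weighting
#'
#' For each class and each of R rounds, a query is drawn from the class's
#' training members, network weights are fitted over the training universe
#' with [fitNetworkWeights()], and every feature with a positive weight
#' gains one point. The final score of a (class, feature) pair is an
#' integer in 0..R. Rounds in which no feature earns a positive weight
#' contribute nothing (a message is emitted).
#'
#' The networks must be restricted to training patients: any network node
#' outside \code{trainIds} is an error, which guarantees held-out patients
#' cannot influence feature scores. Per-class resampling streams are
#' derived from the configured seed and the class label, so results do not
#' depend on class iteration order.
#'
#' @param nets named list of [SimilarityNetwork-class] over training
#'   patients only.
#' @param trainIds training patient identifiers.
#' @param labels data.frame(id, label) covering \code{trainIds}.
#' @param config a [featureSelectionConfig()].
#' @return integer matrix (features x classes) of scores in 0..R, with
#'   attribute \code{"nRounds"}.
#' @export
scoreFeatures <- function(nets, trainIds, labels,
                          config = featureSelectionConfig()) {
  stopifnot(inherits(config, "psnetFSConfig"))
  labels <- .checkLabels(labels)
  if (is.null(names(nets)))
    names(nets) <- vapply(nets, featureName, "")
  allNodes <- unique(unlist(lapply(nets, networkNodes)))
  if (!all(allNodes %in% trainIds))
    stop("networks contain non-training patients; feature scoring must ",
         "run on training-only networks")
  universe <- sort(unique(as.character(trainIds)))
  labels <- labels[labels$id %in% universe, , drop = FALSE]
  classes <- sort(unique(labels$label))
  design <- .pairDesign(nets, universe)

  scores <- matrix(0L, length(nets), length(classes),
                   dimnames = list(names(nets), classes))
  for (cl in classes) {
    members <- sort(labels$id[labels$label == cl])
    .withSeed(.subSeed(config$seed, paste0("class:", cl)), {
      for (r in seq_len(config$nRounds)) {
        q <- resampleQuery(members, config$queryFraction)
        u <- .labelVector(q, universe)
        target <- u[design$i] * u[design$j]
        rows <- if (isTRUE(config$includeNonQueryPairs))
          seq_along(target)
        else which(universe[design$i] %in% q | universe[design$j] %in% q)
        fit <- .ridgePositive(design$X[rows, , drop = FALSE],
                              target[rows], config$lambda)
        if (!length(fit$weights))
          message("class ", cl, " round ", r,
                  ": no feature earned a positive weight")
        scores[names(fit$weights), cl] <-
          scores[names(fit$weights), cl] + 1L
      }
    })
  }
  attr(scores, "nRounds") <- config$nRounds
  scores
}

#' Select features passing a score threshold
#'
#' @param scores matrix from [scoreFeatures()] (features x classes).
#' @param threshold integer; features with score >= threshold are selected
#'   per class. May yield empty sets.
#' @return named list (one element per class) of feature name vectors.
#' @export
selectFeatures <- function(scores, threshold) {
  if (!is.null(attr(scores, "nRounds")) &&
      threshold > attr(scores, "nRounds"))
    stop("threshold exceeds the number of resampling rounds")
  out <- lapply(colnames(scores), function(cl)
    rownames(scores)[scores[, cl] >= threshold])
  names(out) <- colnames(scores)
  out
}

#' Consistency of feature scores across train/test splits
#'
#' For each (class, feature), the consistency score is the largest score s
#' attained in at least \code{minFraction} of the splits; the summary also
#' flags features that attain the maximum possible score in every split
#' (the criterion used to build the display-level integrated network).
#'
#' @param scoreTables list (length >= 2) of score matrices from
#'   [scoreFeatures()], one per split, with identical dimnames.
#' @param minFraction required fraction of splits, default 0.7.
#' @param nRounds maximum possible score R; defaults to the matrices'
#'   \code{"nRounds"} attribute.
#' @return data.frame with columns \code{class}, \code{feature},
#'   \code{consistency}, \code{alwaysMax}.
#' @export
consistencyAcrossSplits <- function(scoreTables, minFraction = 0.7,
                                    nRounds = NULL) {
  if (length(scoreTables) < 2L) stop("need score tables from >= 2 splits")
  if (is.null(nRounds)) nRounds <- attr(scoreTables[[1L]], "nRounds")
  if (is.null(nRounds)) nRounds <- max(unlist(scoreTables))
  feats <- rownames(scoreTables[[1L]])
  classes <- colnames(scoreTables[[1L]])
  nSplit <- length(scoreTables)
  out <- do.call(rbind, lapply(classes, function(cl) {
    perSplit <- vapply(scoreTables, function(m) m[feats, cl],
                       numeric(length(feats)))
    perSplit <- matrix(perSplit, nrow = length(feats))
    cons <- apply(perSplit, 1L, function(x) {
      attained <- vapply(0:nRounds, function(s) mean(x >= s), 0)
      max((0:nRounds)[attained >= minFraction])
    })
    data.frame(class = cl, feature = feats, consistency = as.integer(cons),
               alwaysMax = apply(perSplit, 1L, function(x)
                 all(x == nRounds)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
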