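#' Predictor configuration
#'
#' Settings for the full supervised workflow run by [runPredictor()]:
#' stratified 80:20 train/test splits, optional within-split imputation and
#' lasso prefiltering, per-class feature scoring over resampled queries,
#' classification of held-out patients by label propagation on per-class
#' integrated networks, and performance aggregation across splits.
#'
#' @param trainFraction fraction of each class used for training, default
#'   0.8.
#' @param nSplits number of random train/test splits, default 20.
#' @param featureMode how features (networks) are defined:
#'   \code{"pathway"} (one network per gene set, for gene-level layers),
#'   \code{"datatype"} (one network per layer) or \code{"variable"} (one
#'   network per variable).
#' @param prefilter logical; lasso-prefilter variables within each split
#'   (training data only), default FALSE.
#' @param impute logical; median-impute missing values within each split
#'   (training medians applied to both partitions), default FALSE.
#' @param metric similarity metric passed to [buildDatatypeNetwork()] for
#'   datatype-level features, default \code{"auto"}.
#' @param kernel [kernelConfig()] for exponentially scaled metrics.
#' @param sparsifier [sparsifierConfig()] applied to every network; the
#'   cutoff is replaced by the smallest positive representable weight for
#'   exponentially scaled networks. The default (cutoff 0.3, top 50 edges
#'   per node, at most 3000 edges per network) is the conventional setting
#'   for pathway-level correlation networks; the edge cap activates the
#'   orphan re-attachment rule, which guarantees every patient -- in
#'   particular every held-out patient -- keeps at least one edge and can
#'   therefore be ranked by label propagation.
#' @param databaseMode how each class's classification database is
#'   assembled: \code{"union"} (default) limits it to the union of
#'   features selected for any class, so both class rankings are computed
#'   in the same similarity space and remain comparable even when one
#'   class carries little coherent structure of its own;
#'   \code{"per-class"} restricts each database to that class's own
#'   selected features.
#' @param sizeBounds pathway size bounds, default \code{c(10, 200)}.
#' @param nRounds,queryFraction,threshold feature-scoring settings (see
#'   [featureSelectionConfig()]); defaults 10, 0.8 and 9.
#' @param lambdaRidge ridge penalty for network weighting, default 1.
#' @param lambdaProp label-propagation smoothing, default 1.
#' @param pathwayLayers names of layers expanded into pathway features;
#'   default: the first layer.
#' @param minPairs minimum complete pairs for a Pearson edge.
#' @param seed master seed; every random stage derives its stream from it.
#' @return list with class \code{"psnetPredictorConfig"}.
#' @export
predictorConfig <- function(trainFraction = 0.8, nSplits = 20L,
                            featureMode = c("pathway", "datatype",
                                            "variable"),
                            prefilter = FALSE, impute = FALSE,
                            metric = "auto", kernel = kernelConfig(),
                            sparsifier = sparsifierConfig(cutoff = 0.3,
                                                          topX = 50L,
                                                          maxEdges = 3000L),
                            sizeBounds = c(10L, 200L), nRounds = 10L,
                            queryFraction = 0.8, threshold = 9L,
                            lambdaRidge = 1, lambdaProp = 1,
                            databaseMode = c("union", "per-class"),
                            pathwayLayers = NULL, minPairs = 3L,
                            seed = 42L) {
  stopifnot(trainFraction > 0, trainFraction < 1, nSplits >= 1L)
  structure(list(trainFraction = trainFraction,
                 nSplits = as.integer(nSplits),
                 featureMode = match.arg(featureMode),
                 prefilter = prefilter, impute = impute, metric = metric,
                 kernel = kernel, sparsifier = sparsifier,
                 databaseMode = match.arg(databaseMode),
                 sizeBounds = sizeBounds, nRounds = as.integer(nRounds),
                 queryFraction = queryFraction,
                 threshold = as.integer(threshold),
                 lambdaRidge = lambdaRidge, lambdaProp = lambdaProp,
                 pathwayLayers = pathwayLayers,
                 minPairs = as.integer(minPairs), seed = as.integer(seed)),
            class = "psnetPredictorConfig")
}

#' Stratified train/test split
#'
#' Splits labeled patients into train and test sets preserving per-class
#' proportions to rounding. Uses the session RNG stream (seed it for
#' reproducibility). Every class must have at least 3 members.
#'
#' @param labels data.frame(id, label).
#' @param trainFraction training fraction, default 0.8.
#' @return list with sorted character vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.8) {
  labels <- .checkLabels(labels, minPerClass = 3L)
  stopifnot(trainFraction > 0, trainFraction < 1)
  train <- character(0)
  for (cl in sort(unique(labels$label))) {
    ids <- sort(labels$id[labels$label == cl])
    nTrain <- min(max(round(trainFraction * length(ids)), 2L),
                  length(ids) - 1L)
    train <- c(train, sample(ids, nTrain))
  }
  list(train = sort(train), test = sort(setdiff(labels$id, train)))
}

#' Median imputation within a split
#'
#' Replaces missing entries by the per-variable median of the training
#' partition; the test partition is imputed with the same training medians
#' so no test information leaks into the model. Variables fully missing in
#' the training partition are dropped from both partitions with a warning.
#'
#' @param train a [PatientLayer-class] of training patients.
#' @param test optional [PatientLayer-class] of test patients (same
#'   variables).
#' @return list with elements \code{train}, \code{test} (NULL if absent)
#'   and \code{dropped} (variable names removed).
#' @export
imputeMissing <- function(train, test = NULL) {
  tv <- layerValues(train)
  med <- apply(tv, 2L, stats::median, na.rm = TRUE)
  dropped <- colnames(tv)[is.na(med)]
  if (length(dropped)) {
    warning("dropping variable(s) fully missing in training: ",
            paste(dropped, collapse = ", "))
    tv <- tv[, !colnames(tv) %in% dropped, drop = FALSE]
    med <- med[!names(med) %in% dropped]
  }
  for (j in seq_len(ncol(tv)))
    tv[is.na(tv[, j]), j] <- med[j]
  outTest <- NULL
  if (!is.null(test)) {
    sv <- layerValues(test)[, colnames(tv), drop = FALSE]
    for (j in seq_len(ncol(sv)))
      sv[is.na(sv[, j]), j] <- med[j]
    outTest <- PatientLayer(layerName(test), sv)
  }
  list(train = PatientLayer(layerName(train), tv), test = outTest,
       dropped = dropped)
}

#' Lasso prefilter for variable-level features
#'
#' Ranks a layer's variables by their ability to predict the (binary)
#' class using an L1-penalized logistic model on standardized training
#' data, with the penalty chosen by internal cross-validation on training
#' data only. Variables with a non-zero coefficient at the CV-optimal
#' penalty are retained. Uses the session RNG stream for the CV fold
#' assignment (seed it for reproducibility). May retain nothing, in which
#' case the caller omits the layer for this split.
#'
#' @param train a [PatientLayer-class] of training patients (no missing
#'   values; impute first).
#' @param trainLabels data.frame(id, label) with exactly two classes among
#'   the training patients.
#' @param nfolds internal CV folds, default 5.
#' @return character vector of retained variable names (possibly empty).
#' @export
lassoPrefilter <- function(train, trainLabels, nfolds = 5L) {
  x <- layerValues(train)
  if (anyNA(x)) stop("missing values present; run imputation first")
  trainLabels <- trainLabels[match(rownames(x), trainLabels$id), ,
                             drop = FALSE]
  if (anyNA(trainLabels$label))
    stop("every training patient needs a label")
  y <- factor(trainLabels$label)
  if (nlevels(y) != 2L) stop("lasso prefilter requires binary labels")
  if (ncol(x) < 2L) return(colnames(x))
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = TRUE, foldid = foldid)
  beta <- stats::coef(cv, s = "lambda.min")
  retained <- rownames(beta)[as.numeric(beta) != 0]
  setdiff(retained, "(Intercept)")
}

# Build the (sparsified) feature networks for a set of patients.
# `only`: restrict to the named features (used for class databases);
# NULL builds everything.
.buildFeatureNetworks <- function(layers, sets, config, ids, only = NULL) {
  sub <- lapply(layers, function(ly) {
    keep <- intersect(rownames(layerValues(ly)), ids)
    PatientLayer(layerName(ly), layerValues(ly)[keep, , drop = FALSE])
  })
  pwLayers <- config$pathwayLayers
  if (is.null(pwLayers) && config$featureMode == "pathway")
    pwLayers <- names(sub)[1L]
  nets <- list()
  for (nm in names(sub)) {
    ly <- sub[[nm]]
    if (config$featureMode == "pathway" && nm %in% pwLayers) {
      if (is.null(sets))
        stop("pathway mode requires a GeneSetList")
      pw <- buildPathwayNetworks(ly, sets, sizeBounds = config$sizeBounds,
                                 minPairs = config$minPairs)
      if (!is.null(only)) pw <- pw[intersect(names(pw), only)]
      nets <- c(nets, pw)
    } else if (config$featureMode == "variable") {
      for (v in variableIDs(ly)) {
        fname <- paste0(nm, ":", v)
        if (!is.null(only) && !fname %in% only) next
        one <- PatientLayer(fname,
                            layerValues(ly)[, v, drop = FALSE])
        net <- tryCatch(
          buildDatatypeNetwork(one, metric = config$metric,
                               kernel = config$kernel,
                               minPairs = config$minPairs),
          error = function(e) NULL)
        if (is.null(net)) {
          warning("variable '", fname, "' skipped: degenerate")
          next
        }
        net@featureName <- fname
        nets[[fname]] <- net
      }
    } else {
      if (!is.null(only) && !nm %in% only) next
      nets[[nm]] <- buildDatatypeNetwork(ly, metric = config$metric,
                                         kernel = config$kernel,
                                         minPairs = config$minPairs)
    }
  }
  lapply(nets, function(net) {
    sp <- config$sparsifier
    if (metricName(net) %in% c("eucscale", "pearscale"))
      sp$cutoff <- .Machine$double.xmin
    sparsifyNetwork(net, sp)
  })
}

#' Build a class's classification database over train + test patients
#'
#' After feature selection on training-only networks, the selected
#' networks are recomputed over the union of training and test patients
#' and re-sparsified with the identical configuration, yielding the
#' database on which test patients are ranked. If the selection for the
#' class is empty, the fallback is to use all features (warned loudly) so
#' that every split remains classifiable.
#'
#' @param layers named list of [PatientLayer-class] covering train + test
#'   patients (already imputed/prefiltered if configured).
#' @param selected character vector of selected feature names for this
#'   class (possibly empty, triggering the all-features fallback).
#' @param trainIds,testIds patient identifier vectors.
#' @param sets optional [GeneSetList-class] (pathway mode).
#' @param config a [predictorConfig()].
#' @return named list of sparsified [SimilarityNetwork-class] over
#'   train + test patients.
#' @export
buildClassDatabase <- function(layers, selected, trainIds, testIds,
                               sets = NULL, config = predictorConfig()) {
  only <- selected
  if (!length(selected)) {
    warning("empty feature selection for this class; ",
            "falling back to all features")
    only <- NULL
  }
  .buildFeatureNetworks(layers, sets, config, c(trainIds, testIds),
                        only = only)
}

#' Classify held-out patients against per-class databases
#'
#' For each class, the class's selected networks are combined by uniform
#' averaging and label propagation is run with all of that class's
#' training members as the query. Every patient's propagation rank is
#' rescaled to a normalized rank \eqn{r = 1 - (rank - 1)/(n - 1)} in
#' [0, 1] (1 = most query-like), which is comparable across class
#' databases. A test patient is assigned the class with the highest
#' normalized rank, ties broken by lexicographically smallest class label.
#' For binary problems the continuous decision score is the difference of
#' normalized ranks, first class minus second (classes in sorted order).
#'
#' @param databases named list: class label -> list of
#'   [SimilarityNetwork-class] over train + test patients.
#' @param trainLabels data.frame(id, label) for training patients only.
#' @param testIds held-out patient identifiers.
#' @param lambdaProp label-propagation smoothing, default 1.
#' @return data.frame with one row per test patient: \code{id},
#'   \code{predicted}, one \code{rank_<class>} column per class and, for
#'   binary problems, \code{decision}.
#' @export
classifyPatients <- function(databases, trainLabels, testIds,
                             lambdaProp = 1) {
  trainLabels <- .checkLabels(trainLabels)
  classes <- sort(names(databases))
  if (!all(sort(unique(trainLabels$label)) == classes))
    stop("databases must cover exactly the training classes")
  normRank <- matrix(NA_real_, length(testIds), length(classes),
                     dimnames = list(testIds, classes))
  for (cl in classes) {
    net <- combineNetworks(databases[[cl]],
                           name = paste0("integrated_", cl))
    universe <- sort(networkNodes(net))
    query <- sort(intersect(trainLabels$id[trainLabels$label == cl],
                            universe))
    y <- labelBias(query, universe)
    prop <- propagateLabels(net, y, lambdaProp)
    n <- length(universe)
    r <- 1 - (prop$ranks - 1) / (n - 1)
    missing <- setdiff(testIds, universe)
    if (length(missing))
      stop("test patient(s) absent from class database: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    normRank[, cl] <- r[testIds]
  }
  predicted <- classes[apply(normRank, 1L, which.max)]  # ties -> first (lexicographic)
  out <- data.frame(id = testIds, predicted = predicted,
                    stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("rank_", cl)]] <- normRank[, cl]
  if (length(classes) == 2L)
    out$decision <- normRank[, 1L] - normRank[, 2L]
  rownames(out) <- NULL
  out
}

#' Classifier performance: AUROC, AUPR, accuracy
#'
#' AUROC by the rank (Wilcoxon) method with tied scores counted 0.5; AUPR
#' by step integration of the precision-recall curve over distinct score
#' thresholds; accuracy as the fraction of correct assignments when
#' \code{predicted} is supplied. Multiclass truth is handled one-vs-rest
#' with macro-averaged AUROC/AUPR.
#'
#' @param scores numeric decision scores (higher = more positive-class).
#'   For multiclass, a matrix with one column per class.
#' @param truth character vector of true labels.
#' @param positiveClass label treated as positive for binary problems;
#'   default the lexicographically first label.
#' @param predicted optional character vector of predicted labels.
#' @return list with \code{auroc}, \code{aupr} and \code{accuracy}
#'   (\code{NA} if \code{predicted} missing).
#' @export
evaluatePerformance <- function(scores, truth, positiveClass = NULL,
                                predicted = NULL) {
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  if (length(classes) < 2L)
    stop("AUROC undefined: truth contains a single class")
  if (is.matrix(scores)) {
    per <- lapply(colnames(scores), function(cl)
      evaluatePerformance(scores[, cl], ifelse(truth == cl, cl, "rest"),
                          positiveClass = cl))
    auroc <- mean(vapply(per, `[[`, 0, "auroc"))
    aupr <- mean(vapply(per, `[[`, 0, "aupr"))
  } else {
    if (length(classes) != 2L)
      stop("vector scores require binary truth; supply a score matrix")
    if (is.null(positiveClass)) positiveClass <- classes[1L]
    pos <- truth == positiveClass
    auroc <- .aurocRank(scores, pos)
    aupr <- .auprStep(scores, pos)
  }
  acc <- if (is.null(predicted)) NA_real_ else mean(predicted == truth)
  list(auroc = auroc, aupr = aupr, accuracy = acc)
}

.aurocRank <- function(scores, pos) {
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  stopifnot(nPos > 0, nNeg > 0)
  r <- rank(scores)  # midranks: ties count 0.5
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.auprStep <- function(scores, pos) {
  ord <- order(-scores)
  s <- scores[ord]
  p <- pos[ord]
  nPos <- sum(p)
  # evaluate at the end of each tied-score block
  blockEnd <- which(diff(s) != 0)
  blockEnd <- c(blockEnd, length(s))
  tp <- cumsum(p)[blockEnd]
  fp <- cumsum(!p)[blockEnd]
  recall <- tp / nPos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Run the full predictor across stratified train/test splits
#'
#' Orchestrates, per split: stratified split, optional imputation and
#' lasso prefiltering (training partition only), construction of
#' training-only feature networks, resampled feature scoring per class,
#' selection at the configured threshold, recomputation of each class's
#' selected networks over train + test, classification of the held-out
#' patients by label propagation, and evaluation. All randomness derives
#' from \code{config$seed}, so identical configurations reproduce
#' identical reports. A split that fails is reported with a warning and
#' excluded from the aggregates.
#'
#' @param layers named list of [PatientLayer-class].
#' @param labels data.frame(id, label); every labeled patient should be
#'   present in the layers.
#' @param sets optional [GeneSetList-class] (required for pathway mode).
#' @param config a [predictorConfig()].
#' @return object of class \code{"psnetReport"}: list with
#'   \code{predictions} (per-split data.frames including the truth),
#'   \code{scoreTables} (per-split feature score matrices),
#'   \code{selected} (per-split selected feature lists), \code{metrics}
#'   (per-split data.frame with auroc/aupr/accuracy) and \code{summary}
#'   (mean and SD of each metric), plus the config.
#' @export
runPredictor <- function(layers, labels, sets = NULL,
                         config = predictorConfig()) {
  stopifnot(inherits(config, "psnetPredictorConfig"))
  labels <- .checkLabels(labels, minPerClass = 3L)
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, layerName, "")
  predictions <- list()
  scoreTables <- list()
  selectedAll <- list()
  metricRows <- list()
  for (s in seq_len(config$nSplits)) {
    res <- tryCatch(
      .runOneSplit(layers, labels, sets, config, s),
      error = function(e) {
        warning("split ", s, " failed and is excluded: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    key <- paste0("split", s)
    predictions[[key]] <- res$predictions
    scoreTables[[key]] <- res$scores
    selectedAll[[key]] <- res$selected
    metricRows[[key]] <- data.frame(split = s, auroc = res$metrics$auroc,
                                    aupr = res$metrics$aupr,
                                    accuracy = res$metrics$accuracy)
  }
  if (!length(metricRows)) stop("every split failed")
  metrics <- do.call(rbind, metricRows)
  rownames(metrics) <- NULL
  summ <- data.frame(
    metric = c("auroc", "aupr", "accuracy"),
    mean = vapply(c("auroc", "aupr", "accuracy"),
                  function(m) mean(metrics[[m]]), 0),
    sd = vapply(c("auroc", "aupr", "accuracy"),
                function(m) stats::sd(metrics[[m]]), 0),
    row.names = NULL)
  structure(list(predictions = predictions, scoreTables = scoreTables,
                 selected = selectedAll, metrics = metrics,
                 summary = summ, config = config),
            class = "psnetReport")
}

.runOneSplit <- function(layers, labels, sets, config, s) {
  splitSeed <- .subSeed(config$seed, paste0("split:", s))
  sp <- .withSeed(splitSeed, stratifiedSplit(labels, config$trainFraction))
  trainIds <- sp$train
  testIds <- sp$test
  trainLabels <- labels[labels$id %in% trainIds, , drop = FALSE]

  # within-split preprocessing; statistics come from the training rows only
  workLayers <- layers
  if (config$impute) {
    workLayers <- lapply(workLayers, function(ly) {
      v <- layerValues(ly)
      tr <- PatientLayer(layerName(ly),
                         v[intersect(rownames(v), trainIds), , drop = FALSE])
      te <- PatientLayer(layerName(ly),
                         v[intersect(rownames(v), testIds), , drop = FALSE])
      imp <- imputeMissing(tr, te)
      PatientLayer(layerName(ly),
                   rbind(layerValues(imp$train), layerValues(imp$test)))
    })
  }
  if (config$prefilter) {
    workLayers <- Filter(Negate(is.null), lapply(workLayers, function(ly) {
      v <- layerValues(ly)
      tr <- PatientLayer(layerName(ly),
                         v[intersect(rownames(v), trainIds), , drop = FALSE])
      keep <- .withSeed(.subSeed(splitSeed, paste0("lasso:",
                                                   layerName(ly))),
                        lassoPrefilter(tr, trainLabels))
      if (!length(keep)) {
        warning("lasso prefilter retained no variables for layer '",
                layerName(ly), "'; layer omitted this split")
        return(NULL)
      }
      PatientLayer(layerName(ly), v[, keep, drop = FALSE])
    }))
    if (!length(workLayers)) stop("prefilter removed every layer")
  }

  trainNets <- .buildFeatureNetworks(workLayers, sets, config, trainIds)
  fsCfg <- featureSelectionConfig(nRounds = config$nRounds,
                                  queryFraction = config$queryFraction,
                                  selectionThreshold = config$threshold,
                                  seed = .subSeed(splitSeed, "fs"),
                                  lambda = config$lambdaRidge)
  scores <- scoreFeatures(trainNets, trainIds, trainLabels, fsCfg)
  selected <- selectFeatures(scores, config$threshold)

  if (identical(config$databaseMode, "union")) {
    shared <- buildClassDatabase(workLayers,
                                 sort(unique(unlist(selected))),
                                 trainIds, testIds, sets, config)
    databases <- lapply(selected, function(sel) shared)
  } else {
    databases <- lapply(selected, function(sel)
      buildClassDatabase(workLayers, sel, trainIds, testIds, sets,
                         config))
  }
  preds <- classifyPatients(databases, trainLabels, testIds,
                            config$lambdaProp)
  preds$truth <- labels$label[match(preds$id, labels$id)]
  classes <- sort(unique(labels$label))
  scoresForEval <- if (length(classes) == 2L) preds$decision else {
    m <- as.matrix(preds[, paste0("rank_", classes)])
    colnames(m) <- classes
    m
  }
  metrics <- evaluatePerformance(scoresForEval, preds$truth,
                                 predicted = preds$predicted)
  list(predictions = preds, scores = scores, selected = selected,
       metrics = metrics)
}

#' @export
print.psnetReport <- function(x, ...) {
  cat(sprintf("psnet prediction report: %d/%d splits completed\n",
              nrow(x$metrics), x$config$nSplits))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
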