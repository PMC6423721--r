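test_that("dissimilarity conversion is the edge-wise involution 1 - w", {
  e <- data.frame(from = c("a", "b"), to = c("b", "c"),
                  weight = c(1, 0.3))
  net <- SimilarityNetwork("n", nodes = c("a", "b", "c", "d"),
                           edges = e, metricName = "normalized")
  d <- toDissimilarity(net)
  expect_equal(networkEdges(d)$weight, c(0, 0.7))
  # absent edges stay absent; involution returns the original weights
  expect_equal(nrow(networkEdges(d)), 2L)
  expect_equal(networkEdges(toDissimilarity(d))$weight, c(1, 0.3))
  bad <- SimilarityNetwork("n", edges = data.frame(from = "a", to = "b",
                                                   weight = 1.4))
  expect_error(toDissimilarity(bad), "\\[0,1\\]")
})

test_that("the worked 4-node instance gives exact means and exact WMW p", {
  fx <- makeFixture("wmw-4node")
  sep <- classSeparation(fx$net, fx$labels)
  expect_equal(sep$withinMean, 0.1)
  expect_equal(sep$betweenMean, 0.9)
  expect_equal(sep$pValue, 1 / 15)
  expect_equal(sep$nWithinPairs, 2L)
  expect_equal(sep$nBetweenPairs, 4L)
  expect_equal(sep$nUnreachablePairs, 0L)
  # symmetric relabeling that preserves the partition leaves p unchanged
  relab <- fx$labels
  relab$label <- c("B", "B", "A", "A")
  expect_equal(classSeparation(fx$net, relab)$pValue, sep$pValue)
})

test_that("within = between under a symmetric relabeled clique gives p >= 0.5", {
  ids <- paste0("p", 1:6)
  pairs <- t(combn(ids, 2))
  net <- SimilarityNetwork("c", nodes = ids,
    edges = data.frame(from = pairs[, 1], to = pairs[, 2], weight = 0.5),
    metricName = "normalized")
  labels <- data.frame(id = ids, label = rep(c("A", "B"), 3))
  sep <- classSeparation(net, labels)
  expect_equal(sep$withinMean, sep$betweenMean)
  expect_gte(sep$pValue, 0.5)
})

test_that("shortest paths agree with a Floyd-Warshall oracle", {
  set.seed(61)
  for (rep in 1:4) {
    net <- randomNetwork(12, p = 0.35)
    D <- oracleShortestPaths(net)
    ids <- sort(networkNodes(net))
    labels <- data.frame(id = ids,
                         label = rep(c("A", "B"), length.out = 12))
    # recompute the separation means from the oracle matrix
    lab <- labels$label
    same <- outer(lab, lab, "==")
    up <- upper.tri(D)
    w <- D[up & same]; b <- D[up & !same]
    sep <- classSeparation(net, labels)
    expect_equal(sep$withinMean, mean(w[is.finite(w)]), tolerance = 1e-12)
    expect_equal(sep$betweenMean, mean(b[is.finite(b)]), tolerance = 1e-12)
    expect_equal(sep$nUnreachablePairs,
                 sum(!is.finite(c(w, b))))
  }
})

test_that("unreachable pairs are excluded and counted, not assigned a distance", {
  # two components; one cross edge keeps some between pairs reachable
  e <- data.frame(from = c("a", "c", "b"), to = c("b", "d", "c"),
                  weight = c(0.9, 0.8, 0.5))
  net <- SimilarityNetwork("n", nodes = letters[1:5], edges = e,
                           metricName = "normalized")
  labels <- data.frame(id = letters[1:5],
                       label = c("A", "A", "B", "B", "A"))
  # e is isolated: its 4 pairs are unreachable and must be excluded
  sep <- classSeparation(net, labels)
  expect_equal(sep$nUnreachablePairs, 4L)
  expect_equal(sep$nWithinPairs + sep$nBetweenPairs, 6L)
})

test_that("fully cross-unreachable graphs raise rather than fabricate distances", {
  e <- data.frame(from = c("a", "c"), to = c("b", "d"),
                  weight = c(0.9, 0.8))
  net <- SimilarityNetwork("n", nodes = letters[1:4], edges = e,
                           metricName = "normalized")
  labels <- data.frame(id = letters[1:4], label = c("A", "A", "B", "B"))
  expect_error(classSeparation(net, labels), "unreachable")
})

test_that("large-sample WMW branch matches the tie-corrected normal test", {
  set.seed(71)
  w <- runif(30); b <- runif(40) + 0.2
  p <- psnet:::.wmwLess(w, b)
  expect_equal(p, suppressWarnings(
    wilcox.test(w, b, alternative = "less", exact = FALSE,
                correct = TRUE)$p.value))
  # exact branch agrees with wilcox.test when there are no ties
  w2 <- c(0.11, 0.23, 0.31); b2 <- c(0.42, 0.55, 0.6, 0.77)
  expect_equal(psnet:::.wmwLess(w2, b2),
               wilcox.test(w2, b2, alternative = "less",
                           exact = TRUE)$p.value)
})

test_that("integrated top features average the passing networks", {
  mk <- function(x) {
    m <- matrix(as.integer(x), length(x), 1,
                dimnames = list(paste0("f", seq_along(x)), "A"))
    attr(m, "nRounds") <- 10L
    m
  }
  nets <- list(
    f1 = SimilarityNetwork("f1", nodes = c("a", "b"),
      edges = data.frame(from = "a", to = "b", weight = 0.4),
      metricName = "normalized"),
    f2 = SimilarityNetwork("f2", nodes = c("a", "b"),
      edges = data.frame(from = "a", to = "b", weight = 0.8),
      metricName = "normalized"))
  tabs <- list(mk(c(10, 10)), mk(c(10, 10)))
  top <- integrateTopFeatures(tabs, nets)
  expect_equal(networkEdges(top)$weight, 0.6)
  # only f1 passes -> identity
  tabs2 <- list(mk(c(10, 3)), mk(c(10, 7)))
  top2 <- integrateTopFeatures(tabs2, nets)
  expect_equal(networkEdges(top2)$weight, 0.4)
  tabs3 <- list(mk(c(2, 3)), mk(c(1, 7)))
  expect_error(integrateTopFeatures(tabs3, nets), "relax")
})

test_that("display filters keep the contracted edge counts", {
  # 10 equal-weight edges, distance mode at 40% -> exactly 4 survive
  ids <- paste0("p", 1:5)
  pairs <- t(combn(ids, 2))
  net <- SimilarityNetwork("d", nodes = ids,
    edges = data.frame(from = pairs[, 1], to = pairs[, 2], weight = 0.5),
    metricName = "normalized")
  out <- exportDisplayNetwork(net, "distance")
  expect_equal(nrow(networkEdges(out)), 4L)
  # deterministic tie rule: first by endpoints
  expect_identical(networkEdges(out)$from, c("p1", "p1", "p1", "p1"))

  # figure mode: w < 0.7 excluded, then top 20% per node (ceiling)
  hub <- sprintf("l%02d", 1:10)
  e <- rbind(data.frame(from = "hub", to = hub,
                        weight = seq(0.95, 0.75, length.out = 10)),
             data.frame(from = "hub", to = "weak", weight = 0.65))
  netF <- SimilarityNetwork("f", nodes = c("hub", hub, "weak"),
                            edges = e, metricName = "normalized")
  f <- withr::local_tempfile()
  outF <- exportDisplayNetwork(netF, "figure", path = f)
  eo <- networkEdges(outF)
  # the 0.65 edge is gone; hub keeps ceiling(0.2 * 10) = 2 of its own,
  # but every leaf's top list retains its single edge (endpoint union)
  expect_false(any(eo$weight < 0.7))
  expect_equal(nrow(eo), 10L)
  expect_true(file.exists(f) && file.exists(paste0(f, ".nodes")))
})
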