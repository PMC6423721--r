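test_that("label bias follows the mean-label formula", {
  u <- sprintf("p%02d", 1:12)
  y <- labelBias(u[1:6], u)
  expect_equal(unname(y[u[1]]), 1)
  expect_equal(unname(y[u[7]]), 0)  # balanced case
  y2 <- labelBias(u[1:3], u)
  expect_equal(unname(y2[u[4]]), -0.5)  # (3 - 9) / 12
  expect_error(labelBias(u, u), "non-query")
  expect_error(labelBias(u[1], u), "at least 2")
})

test_that("weight fitting matches the dense ridge oracle on the two-clique fixture", {
  fx <- makeFixture("two-cliques-6")
  fit <- fitNetworkWeights(fx$nets, fx$query, fx$universe, lambda = 1)
  oracle <- oracleRidgeWeights(fx$nets, fx$query, fx$universe, lambda = 1)
  # only the informative clique network earns a positive weight
  expect_named(fit$weights, "A")
  expect_setequal(fit$dropped, c("B", "C"))
  expect_equal(fit$weights[["A"]], oracle[["A"]], tolerance = 1e-10)
  # including non-query pairs is the documented toggle; the oracle agrees
  fit2 <- fitNetworkWeights(fx$nets, fx$query, fx$universe, lambda = 1,
                            includeNonQueryPairs = TRUE)
  oracle2 <- oracleRidgeWeights(fx$nets, fx$query, fx$universe, 1,
                                includeNonQueryPairs = TRUE)
  expect_equal(fit2$weights[["A"]], oracle2[["A"]], tolerance = 1e-10)
})

test_that("duplicated networks share the weight the oracle assigns", {
  fx <- makeFixture("two-cliques-6")
  dup <- list(A1 = fx$nets$A, A2 = fx$nets$A, B = fx$nets$B)
  fit <- fitNetworkWeights(dup, fx$query, fx$universe, lambda = 1)
  oracle <- oracleRidgeWeights(dup, fx$query, fx$universe, lambda = 1)
  expect_equal(sum(fit$weights[c("A1", "A2")]),
               sum(oracle[c("A1", "A2")]), tolerance = 1e-6)
  # in the vanishing-penalty limit the duplicate weights sum to the
  # single-network coefficient (ridge shrinkage is what separates them)
  tiny <- 1e-8
  fitDup <- fitNetworkWeights(dup[1:2], fx$query, fx$universe,
                              lambda = tiny)
  fitOne <- fitNetworkWeights(dup[1], fx$query, fx$universe,
                              lambda = tiny)
  expect_equal(sum(fitDup$weights), sum(fitOne$weights),
               tolerance = 1e-6)
})

test_that("weight fitting is invariant to common edge-weight rescaling", {
  set.seed(41)
  # all three networks share the node ids randomNetwork generates
  nets <- list(a = randomNetwork(12, 0.5, "a"),
               b = randomNetwork(12, 0.5, "b"),
               c = randomNetwork(12, 0.5, "c"))
  ids <- networkNodes(nets$a)
  q <- ids[1:5]
  w1 <- fitNetworkWeights(nets, q, ids)
  scaled <- lapply(nets, function(n) {
    e <- networkEdges(n); e$weight <- e$weight * 0.25
    SimilarityNetwork(featureName(n), nodes = ids, edges = e,
                      metricName = "normalized")
  })
  w2 <- fitNetworkWeights(scaled, q, ids)
  expect_identical(names(w1$weights), names(w2$weights))
  expect_identical(sort(w1$dropped), sort(w2$dropped))
})

test_that("uniform combination averages edge weights over members", {
  n1 <- SimilarityNetwork("n1", nodes = c("a", "b", "c"),
                          edges = data.frame(from = "a", to = "b",
                                             weight = 0.4),
                          metricName = "normalized")
  n2 <- SimilarityNetwork("n2", nodes = c("a", "b", "c"),
                          edges = data.frame(from = c("a", "b"),
                                             to = c("b", "c"),
                                             weight = c(0.8, 0.6)),
                          metricName = "normalized")
  one <- combineNetworks(list(n1 = n1))
  expect_equal(networkEdges(one)$weight, 0.4)
  both <- combineNetworks(list(n1 = n1, n2 = n2))
  e <- networkEdges(both)
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 0.6)
  # absent edge contributes zero
  expect_equal(e$weight[e$from == "b" & e$to == "c"], 0.3)
  # weights (2, 0) reduce to the first network under normalization
  w20 <- combineNetworks(list(n1 = n1, n2 = n2),
                         weights = c(n1 = 2, n2 = 0))
  expect_equal(networkEdges(w20), networkEdges(n1))
  expect_error(combineNetworks(list()), "no networks")
})

test_that("label propagation solves the smoothing system exactly", {
  # edgeless network: no smoothing, f = y
  ids <- paste0("p", 1:5)
  empty <- SimilarityNetwork("e", nodes = ids)
  y <- labelBias(ids[1:2], ids)
  p <- propagateLabels(empty, y)
  expect_equal(p$scores, y)
  expect_true(all(sort(p$ranks) == 1:5))
  # exact ties broken by ascending patient ID
  expect_true(all(diff(p$ranks[ids[3:5]]) == 1))

  # two disconnected cliques: query clique strictly outranks the other
  fx <- makeFixture("two-cliques-6")
  ids10 <- sprintf("q%02d", 1:10)
  clique <- function(m) {
    pr <- t(combn(m, 2)); data.frame(from = pr[, 1], to = pr[, 2],
                                     weight = 1)
  }
  net <- SimilarityNetwork("cl", nodes = ids10,
                           edges = rbind(clique(ids10[1:5]),
                                         clique(ids10[6:10])),
                           metricName = "normalized")
  y <- labelBias(ids10[1:3], ids10)
  p <- propagateLabels(net, y)
  expect_gt(min(p$scores[ids10[1:5]]), max(p$scores[ids10[6:10]]))
  expect_equal(p$scores, oraclePropagate(net, y, 1), tolerance = 1e-12)

  # lambda -> 0 recovers the bias
  p0 <- propagateLabels(net, y, lambdaProp = 1e-8)
  expect_equal(p0$scores, y, tolerance = 1e-6)

  # automorphism symmetry: swapping two symmetric non-query nodes leaves
  # their scores equal
  expect_equal(unname(p$scores[ids10[6]]), unname(p$scores[ids10[7]]))
})

test_that("iterative propagation matches the closed form", {
  set.seed(77)
  for (rep in 1:5) {
    net <- randomNetwork(50, p = 0.15)
    ids <- networkNodes(net)
    y <- labelBias(sample(ids, 10), ids)
    direct <- propagateLabels(net, y)
    iter <- iterativePropagate(net, y, tol = 1e-12)
    expect_lt(max(abs(iter$scores - direct$scores)), 1e-8)
  }
  # tiny path graph at tight tolerance
  path <- SimilarityNetwork("p", nodes = paste0("v", 1:5),
    edges = data.frame(from = paste0("v", 1:4), to = paste0("v", 2:5),
                       weight = 0.5), metricName = "normalized")
  y <- labelBias(c("v1", "v2"), paste0("v", 1:5))
  expect_lt(max(abs(iterativePropagate(path, y, tol = 1e-12)$scores -
                    propagateLabels(path, y)$scores)), 1e-10)
  expect_error(iterativePropagate(path, y, tol = 1e-12, maxIter = 1),
               "converge")
})

test_that("query members fill the top ranks when they form their own component", {
  ids <- sprintf("p%02d", 1:9)
  clique <- function(m, w) {
    pr <- t(combn(m, 2)); data.frame(from = pr[, 1], to = pr[, 2],
                                     weight = w)
  }
  net <- SimilarityNetwork("c", nodes = ids,
                           edges = rbind(clique(ids[1:4], 0.9),
                                         clique(ids[5:9], 0.9)),
                           metricName = "normalized")
  y <- labelBias(ids[1:4], ids)
  p <- propagateLabels(net, y)
  expect_setequal(names(sort(p$ranks)[1:4]), ids[1:4])
})
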