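# Independent oracles used across the suite. These re-derive expected
# values from first principles (explicit pair enumeration, dense linear
# algebra, Floyd-Warshall) rather than calling the package's own code
# paths.

# Explicit dense ridge solve over enumerated patient pairs, with its own
# drop-and-refit loop. Adjacency weights are looked up straight from each
# network's edge table.
oracleRidgeWeights <- function(nets, query, universe, lambda,
                               includeNonQueryPairs = FALSE) {
  n <- length(universe)
  nq <- length(query)
  u <- ifelse(universe %in% query, (n - nq) / n, -nq / n)
  lookup <- function(net, a, b) {
    e <- networkEdges(net)
    hit <- (e$from == a & e$to == b) | (e$from == b & e$to == a)
    if (any(hit)) e$weight[hit][1L] else 0
  }
  rows <- list()
  tgt <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    qi <- universe[i] %in% query
    qj <- universe[j] %in% query
    if (!includeNonQueryPairs && !qi && !qj) next
    rows[[length(rows) + 1L]] <-
      vapply(nets, lookup, 0, a = universe[i], b = universe[j])
    tgt <- c(tgt, u[i] * u[j])
  }
  X <- do.call(rbind, rows)
  colnames(X) <- names(nets)
  keep <- seq_len(ncol(X))
  repeat {
    if (!length(keep)) return(stats::setNames(numeric(0), character(0)))
    M <- cbind(1, X[, keep, drop = FALSE])
    P <- diag(c(0, rep(lambda, length(keep))))
    beta <- solve(t(M) %*% M + P, t(M) %*% tgt)[-1L, 1L]
    if (all(beta > 1e-10))
      return(stats::setNames(as.numeric(beta), colnames(X)[keep]))
    keep <- keep[beta > 1e-10]
  }
}

# Dense closed-form propagation solve written independently (explicit
# Laplacian assembly by loops over the edge table).
oraclePropagate <- function(net, bias, lambdaProp) {
  ids <- names(bias)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- networkEdges(net)
  for (k in seq_len(nrow(e))) {
    W[e$from[k], e$to[k]] <- e$weight[k]
    W[e$to[k], e$from[k]] <- e$weight[k]
  }
  deg <- rowSums(W)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) L[i, j] <- if (deg[i] > 0) 1 else 0
    else if (deg[i] > 0 && deg[j] > 0)
      L[i, j] <- -W[i, j] / sqrt(deg[i] * deg[j])
  }
  stats::setNames(as.numeric(solve(diag(n) + lambdaProp * L,
                                   as.numeric(bias))), ids)
}

# All-pairs shortest paths by Floyd-Warshall on the 1-similarity distances.
oracleShortestPaths <- function(net) {
  ids <- sort(networkNodes(net))
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  e <- networkEdges(net)
  for (k in seq_len(nrow(e))) {
    d <- 1 - e$weight[k]
    D[e$from[k], e$to[k]] <- d
    D[e$to[k], e$from[k]] <- d
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Random weighted graph over n nodes with edge probability p.
randomNetwork <- function(n, p = 0.3, name = "rand",
                          metric = "normalized") {
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  e <- data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                  weight = stats::runif(sum(keep)),
                  stringsAsFactors = FALSE)
  SimilarityNetwork(name, nodes = ids, edges = e, metricName = metric)
}

# Small planted cohort for fast module-level recovery tests: one strongly
# predictive set among a handful of noise sets.
smallCohort <- function(seed, nPerClass = 20L, nSets = 6L, setSize = 15L,
                        effectSize = 2) {
  simulateCohort(simulationSpec(
    nPerClass = nPerClass, nGenes = nSets * setSize, nSets = nSets,
    setSize = setSize, nPredictive = 1L, effectSize = effectSize,
    nClinicalVars = 0L, seed = seed))
}
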