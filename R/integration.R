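#' Bias vector for a query over a patient universe
#'
#' Query ("+") patients receive bias +1; all other patients receive the
#' mean label \eqn{b = (n_q - n_o) / (n_q + n_o)}, where \eqn{n_q} and
#' \eqn{n_o} are the query and non-query counts. In the balanced case the
#' bias is mean-centred (b = 0).
#'
#' @param queryIds patient subset (at least 2, strictly inside universe).
#' @param universeIds all patients in the database.
#' @return named numeric vector over \code{universeIds}.
#' @export
labelBias <- function(queryIds, universeIds) {
  .checkQuery(queryIds, universeIds)
  nq <- length(queryIds)
  no <- length(universeIds) - nq
  y <- rep((nq - no) / (nq + no), length(universeIds))
  names(y) <- universeIds
  y[queryIds] <- 1
  y
}

.checkQuery <- function(queryIds, universeIds) {
  if (anyDuplicated(queryIds) || anyDuplicated(universeIds))
    stop("query and universe identifiers must be unique")
  if (!all(queryIds %in% universeIds))
    stop("query must be a subset of the universe")
  if (length(queryIds) < 2L)
    stop("query must contain at least 2 patients")
  if (length(universeIds) - length(queryIds) < 1L)
    stop("universe must contain at least one non-query patient")
  invisible(TRUE)
}

# zero-mean label vector used in the regression target:
# u_i = n_o/n for query members, -n_q/n otherwise
.labelVector <- function(queryIds, universeIds) {
  nq <- length(queryIds)
  n <- length(universeIds)
  u <- rep(-nq / n, n)
  names(u) <- universeIds
  u[queryIds] <- (n - nq) / n
  u
}

# design matrix over unordered patient pairs: one column per network,
# entries are the networks' edge weights (0 where absent). Returned with
# the pair index so targets can be recomputed cheaply per query.
.pairDesign <- function(nets, universe) {
  n <- length(universe)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  X <- matrix(0, nrow(idx), length(nets))
  colnames(X) <- names(nets)
  for (k in seq_along(nets)) {
    A <- .adjacencyMatrix(nets[[k]], universe)
    X[, k] <- A[idx]
  }
  list(X = X, i = idx[, 1L], j = idx[, 2L], universe = universe)
}

# ridge solve with unpenalized intercept and drop-and-refit enforcement of
# positive network weights. XtX/Xty exclude the intercept; it is appended
# here. Returns named weights (possibly empty) and the dropped features.
.ridgePositive <- function(X, target, lambda, dropTol = 1e-10) {
  p <- ncol(X)
  keep <- seq_len(p)
  ones <- rep(1, nrow(X))
  repeat {
    if (!length(keep))
      return(list(weights = stats::setNames(numeric(0), character(0)),
                  dropped = colnames(X)))
    Xk <- X[, keep, drop = FALSE]
    M <- cbind(1, Xk)
    A <- crossprod(M)
    diag(A)[-1L] <- diag(A)[-1L] + lambda
    beta <- solve(A, crossprod(M, target))[, 1L]
    w <- beta[-1L]
    bad <- which(w <= dropTol)
    if (!length(bad)) {
      weights <- stats::setNames(as.numeric(w), colnames(Xk))
      return(list(weights = weights,
                  dropped = setdiff(colnames(X), colnames(Xk))))
    }
    keep <- keep[-bad]
  }
}

#' Fit non-negative network weights against a query-derived target
#'
#' The query-driven network weighting at the heart of the recommender:
#' each candidate network's off-diagonal adjacency entries (one row per
#' unordered patient pair, plus an unpenalized intercept) are regressed by
#' ridge regression onto the target \eqn{t_{ij} = u_i u_j}, where \eqn{u}
#' is the zero-mean label vector (\eqn{u_i = n_o/n} for query members,
#' \eqn{-n_q/n} otherwise). A network enriched for query-query edges and
#' depleted of cross edges earns a positive coefficient. Non-positive
#' coefficients are enforced by drop-and-refit: any network whose fitted
#' coefficient is not positive is removed and the reduced system re-solved
#' until all remaining coefficients are positive (the feature set strictly
#' shrinks, so the loop terminates). If no network survives, an empty
#' weight set is returned with a message (the features simply score zero
#' for this query).
#'
#' @param nets named list of [SimilarityNetwork-class] sharing the
#'   universe (patients absent from a network are treated as isolated).
#' @param queryIds query ("+") patients, at least 2.
#' @param universeIds all patients; defaults to the sorted union of the
#'   networks' nodes.
#' @param lambda positive ridge penalty, default 1.
#' @param includeNonQueryPairs logical; include pairs among non-query
#'   patients in the target (their target value is positive). Default
#'   FALSE: non-query patients are not known to share a class, so edges
#'   among them are treated as uninformative rather than rewarded, which
#'   sharpens the contrast the regression sees and empirically suppresses
#'   spurious positive weights for uninformative networks.
#' @param dropTol coefficients at or below this value count as non-positive.
#' @return list with elements \code{weights} (named positive numerics),
#'   \code{dropped} (feature names with non-positive fit) and
#'   \code{lambda}.
#' @export
fitNetworkWeights <- function(nets, queryIds, universeIds = NULL,
                              lambda = 1, includeNonQueryPairs = FALSE,
                              dropTol = 1e-10) {
  stopifnot(lambda > 0)
  if (is.null(names(nets)))
    names(nets) <- vapply(nets, featureName, "")
  if (is.null(universeIds))
    universeIds <- sort(unique(unlist(lapply(nets, networkNodes))))
  .checkQuery(queryIds, universeIds)
  d <- .pairDesign(nets, universeIds)
  u <- .labelVector(queryIds, universeIds)
  target <- u[d$i] * u[d$j]
  rows <- if (includeNonQueryPairs) seq_along(target)
          else which(universeIds[d$i] %in% queryIds |
                     universeIds[d$j] %in% queryIds)
  fit <- .ridgePositive(d$X[rows, , drop = FALSE], target[rows], lambda)
  if (!length(fit$weights))
    message("no network received a positive weight for this query")
  c(fit, list(lambda = lambda))
}

#' Combine networks into a single integrated network
#'
#' Weighted-average combination: the integrated edge weight is
#' \eqn{\sum_k \alpha_k w_k(a,b) / \sum_k \alpha_k}, a missing edge
#' contributing 0. With \code{weights = NULL} all networks get
#' \eqn{\alpha = 1} (plain average), the combination used to build each
#' class's integrated network for prediction and display; fitted weights
#' may be supplied instead. Output weights stay in [0, 1] when all inputs
#' are.
#'
#' @param nets named list of [SimilarityNetwork-class].
#' @param weights optional named non-negative weights (names matched to
#'   \code{names(nets)}); networks not named are excluded.
#' @param name name for the combined network.
#' @return A [SimilarityNetwork-class] over the union of input nodes.
#' @export
combineNetworks <- function(nets, weights = NULL, name = "integrated") {
  if (!length(nets)) stop("no networks to combine")
  if (is.null(names(nets)))
    names(nets) <- vapply(nets, featureName, "")
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(nets)), names(nets))
  } else {
    if (any(weights < 0)) stop("combination weights must be non-negative")
    bad <- setdiff(names(weights), names(nets))
    if (length(bad)) stop("unknown network(s): ", paste(bad, collapse = ", "))
    nets <- nets[names(weights)]
  }
  total <- sum(weights)
  if (total <= 0) stop("combination weights must sum to a positive value")
  universe <- sort(unique(unlist(lapply(nets, networkNodes))))
  M <- matrix(0, length(universe), length(universe),
              dimnames = list(universe, universe))
  for (k in seq_along(nets))
    M <- M + weights[[k]] * .adjacencyMatrix(nets[[k]], universe)
  M <- M / total
  SimilarityNetwork(name, nodes = universe,
                    edges = .edgesFromMatrix(M, dropZero = TRUE),
                    metricName = "average")
}

# symmetric-normalized Laplacian smoothing operator pieces
.propagationSystem <- function(net, bias, lambdaProp) {
  if (is.null(names(bias))) stop("bias vector must be named by patient")
  universe <- names(bias)
  missingNodes <- setdiff(networkNodes(net), universe)
  if (length(missingNodes))
    stop("bias undefined for node(s): ",
         paste(utils::head(missingNodes, 5L), collapse = ", "))
  W <- .adjacencyMatrix(net, universe)
  if (!all(is.finite(W))) stop("non-finite edge weights")
  deg <- rowSums(W)
  s <- ifelse(deg > 0, 1 / sqrt(deg), 0)  # isolated nodes stay at their bias
  Wn <- W * outer(s, s)
  L <- diag(ifelse(deg > 0, 1, 0)) - Wn
  A <- diag(length(bias)) + lambdaProp * L
  list(A = A, universe = universe)
}

.rankScores <- function(f) {
  ord <- order(-f, names(f))  # ties broken by ascending patient ID
  ranks <- integer(length(f))
  ranks[ord] <- seq_along(f)
  names(ranks) <- names(f)
  ranks
}

#' Label propagation on an integrated network
#'
#' Smooths a query-derived bias vector over the graph by solving the
#' closed form
#' \deqn{f = (I + \lambda L_{sym})^{-1} y,}
#' where \eqn{L_{sym}} is the symmetric-normalized graph Laplacian of the
#' network (isolated nodes have their normalized degree treated as 0 and
#' therefore keep \eqn{f_i = y_i}). Patients are ranked from most to least
#' query-like by descending score, ties broken by ascending patient ID.
#'
#' @param net a [SimilarityNetwork-class].
#' @param bias named bias vector over the universe (see [labelBias()]).
#' @param lambdaProp positive smoothing strength, default 1.
#' @return list of class \code{"psnetPropagation"} with \code{scores}
#'   (named numeric), \code{ranks} (named integer permutation, 1 = most
#'   query-like) and \code{bias}.
#' @export
propagateLabels <- function(net, bias, lambdaProp = 1) {
  stopifnot(lambdaProp > 0)
  sys <- .propagationSystem(net, bias, lambdaProp)
  f <- stats::setNames(as.numeric(solve(sys$A, as.numeric(bias))),
                       sys$universe)
  structure(list(scores = f, ranks = .rankScores(f), bias = bias),
            class = "psnetPropagation")
}

#' Iterative label propagation (conjugate gradient)
#'
#' Solves the same system as [propagateLabels()] by conjugate gradient,
#' suitable for larger universes; the system matrix is symmetric positive
#' definite so CG converges. Errors (reporting the residual) if the
#' residual max-norm does not fall below \code{tol} within \code{maxIter}
#' iterations.
#'
#' @inheritParams propagateLabels
#' @param tol positive convergence tolerance on the residual max-norm.
#' @param maxIter iteration cap; default \code{10 n + 50}.
#' @return list of class \code{"psnetPropagation"}, as [propagateLabels()].
#' @export
iterativePropagate <- function(net, bias, lambdaProp = 1, tol = 1e-10,
                               maxIter = NULL) {
  stopifnot(lambdaProp > 0, tol > 0)
  sys <- .propagationSystem(net, bias, lambdaProp)
  A <- sys$A
  n <- length(bias)
  if (is.null(maxIter)) maxIter <- 10L * n + 50L
  x <- numeric(n)
  r <- as.numeric(bias)
  p <- r
  rs <- sum(r * r)
  iter <- 0L
  while (max(abs(r)) >= tol) {
    iter <- iter + 1L
    if (iter > maxIter)
      stop(sprintf(
        "conjugate gradient did not converge in %d iterations (residual %.3g)",
        maxIter, max(abs(r))))
    Ap <- A %*% p
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * as.numeric(Ap)
    rsNew <- sum(r * r)
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  f <- stats::setNames(as.numeric(x), sys$universe)
  structure(list(scores = f, ranks = .rankScores(f), bias = bias),
            class = "psnetPropagation")
}

#' @export
print.psnetPropagation <- function(x, ...) {
  cat(sprintf("Label propagation over %d patients; top of ranking:\n",
              length(x$scores)))
  top <- names(sort(x$ranks))[seq_len(min(5L, length(x$ranks)))]
  print(round(x$scores[top], 4))
  invisible(x)
}
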