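#' Normalized similarity of two scalar values
#'
#' For a continuous variable with observed range \eqn{[min(G), max(G)]},
#' the similarity of two values is
#' \deqn{S(a, b, G) = 1 - |a - b| / (max(G) - min(G)),}
#' which lies in [0, 1], is symmetric in its arguments and equals 1 iff
#' \eqn{a = b}.
#'
#' @param a,b numeric values (vectorized).
#' @param valueRange numeric length-2 vector \code{c(min, max)} of the
#'   variable over the cohort; \code{max > min} required (a degenerate
#'   variable is an error and should be dropped by the caller).
#' @return similarity weight(s) in [0, 1].
#' @examples
#' normalizedSimilarity(30, 40, c(20, 60))  # 0.75
#' @export
normalizedSimilarity <- function(a, b, valueRange) {
  rng <- valueRange[2L] - valueRange[1L]
  if (!is.finite(rng) || rng <= 0)
    stop("degenerate variable: max(G) must exceed min(G)")
  1 - abs(a - b) / rng
}

#' Mean normalized similarity over a small variable profile
#'
#' Average of per-variable [normalizedSimilarity()] over the non-degenerate
#' variables of a k-variable profile (the similarity used when a data type
#' has five or fewer variables). Degenerate variables (zero range) are
#' dropped with a warning; if all are degenerate an error is raised.
#'
#' @param profileA,profileB numeric vectors of length k.
#' @param ranges 2 x k matrix (rows min, max) or list of length-2 vectors.
#' @return similarity weight in [0, 1].
#' @export
meanNormalizedSimilarity <- function(profileA, profileB, ranges) {
  if (is.list(ranges)) ranges <- vapply(ranges, c, numeric(2L))
  k <- length(profileA)
  stopifnot(length(profileB) == k, ncol(ranges) == k)
  if (k > 5L)
    warning("mean normalized similarity is intended for <= 5 variables; ",
            "got ", k)
  span <- ranges[2L, ] - ranges[1L, ]
  ok <- is.finite(span) & span > 0
  if (!any(ok)) stop("all variables are degenerate (zero range)")
  if (!all(ok))
    warning("dropping ", sum(!ok), " degenerate variable(s)")
  mean(1 - abs(profileA[ok] - profileB[ok]) / span[ok])
}

#' Pearson similarity of two profiles
#'
#' Pearson correlation over pairwise-complete observations, requiring at
#' least \code{minPairs} complete pairs; returns \code{NA} (edge omitted by
#' the network builders) when too few pairs remain or when either profile
#' has zero variance over the complete pairs.
#'
#' @param x,y numeric vectors of equal length; \code{NA}s allowed.
#' @param minPairs minimum number of complete pairs (default 3).
#' @return correlation in [-1, 1], or \code{NA}.
#' @export
pearsonSimilarity <- function(x, y, minPairs = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < minPairs) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Local exponential scaling kernel
#'
#' Converts a distance into a unit-interval similarity through a locally
#' scaled Gaussian kernel,
#' \deqn{w = \exp(-d^2 / (\mu \, \bar\epsilon)),}
#' where the bandwidth \eqn{\bar\epsilon} averages the two patients' local
#' scales and the pair distance itself:
#' \eqn{\bar\epsilon = (\epsilon_i + \epsilon_j + d)/3}. Each patient's
#' local scale \eqn{\epsilon_i} is the mean distance to their k nearest
#' neighbours (computed by the network builders).
#'
#' @param d non-negative distance (vectorized).
#' @param epsI,epsJ local bandwidths of the two patients.
#' @param mu positive scaling factor, default 0.5.
#' @return weight(s) in (0, 1], monotone decreasing in \code{d}.
#' @export
scaledExponentialSimilarity <- function(d, epsI, epsJ, mu = 0.5) {
  if (mu <= 0) stop("mu must be positive")
  ebar <- (epsI + epsJ + d) / 3
  if (any(ebar <= 0)) stop("local bandwidth must be positive")
  exp(-d^2 / (mu * ebar))
}

#' Kernel configuration for exponential scaling
#'
#' @param mu positive scaling factor of the local exponential kernel.
#' @param kNeighbors neighbourhood size used for the local bandwidth
#'   (truncated to n - 1 patients at build time).
#' @return list with class \code{"psnetKernelConfig"}.
#' @export
kernelConfig <- function(mu = 0.5, kNeighbors = 20L) {
  stopifnot(mu > 0, kNeighbors >= 1L)
  structure(list(mu = mu, kNeighbors = as.integer(kNeighbors)),
            class = "psnetKernelConfig")
}

# local bandwidth: mean distance of each patient to its k nearest
# neighbours (excluding self) on distance matrix D
.localBandwidth <- function(D, k) {
  n <- nrow(D)
  k <- min(k, n - 1L)
  vapply(seq_len(n), function(i) mean(sort(D[i, -i])[seq_len(k)]), 0)
}

# similarity matrix (patients x patients) under a scaled exponential kernel
.kernelMatrix <- function(D, kernel) {
  eps <- .localBandwidth(D, kernel$kNeighbors)
  n <- nrow(D)
  E <- (matrix(eps, n, n) + matrix(eps, n, n, byrow = TRUE) + D) / 3
  W <- exp(-D^2 / (kernel$mu * E))
  dimnames(W) <- dimnames(D)
  W
}

# patient-by-patient Pearson matrix with a minimum-complete-pairs rule
.patientCorMatrix <- function(values, minPairs = 3L) {
  R <- suppressWarnings(stats::cor(t(values), use = "pairwise.complete.obs"))
  counts <- tcrossprod(!is.na(values))
  R[counts < minPairs] <- NA_real_
  R
}

#' Build one similarity network for a whole data layer
#'
#' With \code{metric = "auto"} the metric follows the variable count of the
#' layer: Pearson correlation when the layer has six or more variables,
#' average normalized similarity when it has five or fewer. The other
#' choices force a metric: \code{"pearson"}, \code{"normalized"},
#' \code{"eucscale"} (Euclidean distance + local exponential scaling) and
#' \code{"pearscale"} (Pearson distance \eqn{d = 1 - r} + local exponential
#' scaling).
#'
#' Pearson edges use pairwise-complete observations and are omitted when
#' fewer than \code{minPairs} pairs remain or a profile is constant.
#' Normalized-similarity edges average over the variables observed for both
#' patients; degenerate variables (zero range over the layer) are dropped
#' with a warning, and an error is raised if all variables are degenerate.
#'
#' @param layer a [PatientLayer-class] with at least two patients.
#' @param metric one of \code{"auto"}, \code{"pearson"},
#'   \code{"normalized"}, \code{"eucscale"}, \code{"pearscale"}.
#' @param kernel [kernelConfig()] for the scaled metrics.
#' @param minPairs minimum complete pairs for a Pearson edge.
#' @return A [SimilarityNetwork-class] named after the layer.
#' @export
buildDatatypeNetwork <- function(layer, metric = c("auto", "pearson",
                                                   "normalized", "eucscale",
                                                   "pearscale"),
                                 kernel = kernelConfig(), minPairs = 3L) {
  metric <- match.arg(metric)
  v <- layerValues(layer)
  if (nrow(v) < 2L) stop("need at least 2 patients to build a network")
  if (metric == "auto")
    metric <- if (ncol(v) >= 6L) "pearson" else "normalized"
  W <- switch(metric,
    pearson = .patientCorMatrix(v, minPairs),
    normalized = .meanNormalizedMatrix(v),
    eucscale = .kernelMatrix(as.matrix(stats::dist(v)), kernel),
    pearscale = {
      R <- .patientCorMatrix(v, minPairs)
      .kernelMatrix(1 - R, kernel)
    })
  mlabel <- if (metric == "normalized") "meanNormalized" else metric
  SimilarityNetwork(layerName(layer), nodes = rownames(v),
                    edges = .edgesFromMatrix(W, dropZero = FALSE),
                    metricName = mlabel)
}

# pairwise mean normalized similarity matrix over non-degenerate variables;
# pairs with no jointly observed variable get NA (edge omitted)
.meanNormalizedMatrix <- function(values) {
  rng <- apply(values, 2L, range, na.rm = TRUE)
  span <- rng[2L, ] - rng[1L, ]
  ok <- is.finite(span) & span > 0
  if (!any(ok))
    stop("all variables are degenerate (zero range); cannot build network")
  if (!all(ok))
    warning("dropping ", sum(!ok), " degenerate variable(s): ",
            paste(colnames(values)[!ok], collapse = ", "))
  values <- values[, ok, drop = FALSE]
  span <- span[ok]
  n <- nrow(values)
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(values),
                                              rownames(values)))
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    sim <- 1 - abs(outer(x, x, "-")) / span[j]
    obs <- !is.na(sim)
    sim[!obs] <- 0
    acc <- acc + sim
    cnt <- cnt + obs
  }
  S[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  S
}

#' Build one network per pathway from an expression layer
#'
#' For each gene set, pathway-level patient similarity is the Pearson
#' correlation of the two patients' expression vectors restricted to the
#' set's member genes present in the matrix. Sets whose present-gene count
#' falls outside \code{sizeBounds} are skipped (with a message); sets with
#' no genes present are skipped with a warning; if no set survives an
#' error is raised.
#'
#' @param expr a [PatientLayer-class] whose variables are gene symbols.
#' @param sets a [GeneSetList-class].
#' @param sizeBounds inclusive bounds \code{c(lo, hi)} on member genes
#'   present in the matrix; default \code{c(10, 200)}.
#' @param minPairs minimum complete pairs for a Pearson edge.
#' @return named list of [SimilarityNetwork-class], one per surviving set.
#' @export
buildPathwayNetworks <- function(expr, sets, sizeBounds = c(10L, 200L),
                                 minPairs = 3L) {
  v <- layerValues(expr)
  genes <- colnames(v)
  out <- list()
  for (nm in names(geneSets(sets))) {
    members <- intersect(geneSets(sets)[[nm]], genes)
    if (!length(members)) {
      warning("gene set '", nm, "' has no genes in the matrix; skipped")
      next
    }
    if (length(members) < sizeBounds[1L] || length(members) > sizeBounds[2L]) {
      message("gene set '", nm, "' outside size bounds (",
              length(members), " genes present); skipped")
      next
    }
    W <- .patientCorMatrix(v[, members, drop = FALSE], minPairs)
    out[[nm]] <- SimilarityNetwork(nm, nodes = rownames(v),
                                   edges = .edgesFromMatrix(W,
                                                            dropZero = FALSE),
                                   metricName = "pearson")
  }
  if (!length(out))
    stop("no gene set survives the size bounds / gene intersection")
  out
}
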