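# internal helpers shared across modules

# Deterministic sub-seed derived from a master seed and a string salt.
# Kept below 2^31 so it is always a valid R integer seed.
.subSeed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + h * 16807 + 12345) %% 2147483629)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Dense symmetric adjacency matrix of a network over a node universe.
# Patients absent from the network enter as isolated (all-zero) rows.
.adjacencyMatrix <- function(net, universe = NULL) {
  if (is.null(universe)) universe <- sort(networkNodes(net))
  n <- length(universe)
  A <- matrix(0, n, n, dimnames = list(universe, universe))
  e <- networkEdges(net)
  if (nrow(e)) {
    keep <- e$from %in% universe & e$to %in% universe
    e <- e[keep, , drop = FALSE]
    if (nrow(e)) {
      i <- match(e$from, universe)
      j <- match(e$to, universe)
      A[cbind(i, j)] <- e$weight
      A[cbind(j, i)] <- e$weight
    }
  }
  A
}

# Edge list (from < to) from a dense symmetric matrix; entries that are NA
# or (optionally) zero are treated as absent edges.
.edgesFromMatrix <- function(M, dropZero = TRUE) {
  stopifnot(!is.null(rownames(M)))
  idx <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[idx]
  keep <- !is.na(w)
  if (dropZero) keep <- keep & w != 0
  data.frame(from = rownames(M)[idx[keep, 1L]],
             to = colnames(M)[idx[keep, 2L]],
             weight = w[keep], stringsAsFactors = FALSE)
}

# validate a label table: data.frame(id, label), unique ids, >=2 classes,
# every class with >= minPerClass members
.checkLabels <- function(labels, minPerClass = 2L) {
  if (!is.data.frame(labels) || !all(c("id", "label") %in% names(labels)))
    stop("labels must be a data.frame with columns 'id' and 'label'")
  labels$id <- as.character(labels$id)
  labels$label <- as.character(labels$label)
  if (anyDuplicated(labels$id))
    stop("duplicate patient identifiers in label table")
  tab <- table(labels$label)
  if (length(tab) < 2L)
    stop("label table must contain at least two distinct classes")
  if (any(tab < minPerClass))
    stop("every class must have at least ", minPerClass, " members; ",
         paste(names(tab)[tab < minPerClass], collapse = ", "), " too small")
  labels
}
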