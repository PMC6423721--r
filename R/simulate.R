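#' Specification of a synthetic two-class cohort
#'
#' Defines a cohort with a gene-expression layer in which a chosen subset
#' of pathways carries a class-discriminating expression signature, plus
#' optional clinical variables, so every stage of the workflow can be
#' exercised against known ground truth. Baseline expression is standard
#' normal; within each predictive gene set, genes are shifted in class
#' \code{"case"} by the effect size \code{d} with alternating sign across
#' the set's genes, so each predictive gene has a standardized
#' between-class difference of magnitude \code{d} while the set's genes
#' jointly form a signature that raises within-class correlation (a shift
#' that was uniform across a set would cancel out of patient-wise Pearson
#' correlation). Gene sets are non-overlapping blocks. Missingness, when
#' requested, is completely at random.
#'
#' @param nPerClass patients per class, default 60.
#' @param nGenes total genes, default 600.
#' @param nSets number of gene sets, default 30.
#' @param setSize genes per set, default 20 (\code{nSets * setSize} must
#'   not exceed \code{nGenes}).
#' @param nPredictive number of predictive sets, default 3.
#' @param effectSize standardized per-gene mean-shift magnitude d,
#'   default 1.5.
#' @param nClinicalVars clinical variables, default 2.
#' @param clinicalEffects numeric vector of per-variable mean shifts in
#'   class case (recycled); default 0 (pure noise).
#' @param missingRate MCAR missingness fraction in [0, 1), default 0.
#' @param seed RNG seed.
#' @return list with class \code{"psnetSimulationSpec"}.
#' @export
simulationSpec <- function(nPerClass = 60L, nGenes = 600L, nSets = 30L,
                           setSize = 20L, nPredictive = 3L,
                           effectSize = 1.5, nClinicalVars = 2L,
                           clinicalEffects = 0, missingRate = 0,
                           seed = 42L) {
  stopifnot(nPerClass >= 2L, effectSize >= 0, missingRate >= 0,
            missingRate < 1, nPredictive <= nSets)
  if (nSets * setSize > nGenes)
    stop("nGenes too small for the requested gene sets")
  structure(list(nPerClass = as.integer(nPerClass),
                 nGenes = as.integer(nGenes), nSets = as.integer(nSets),
                 setSize = as.integer(setSize),
                 nPredictive = as.integer(nPredictive),
                 effectSize = effectSize,
                 nClinicalVars = as.integer(nClinicalVars),
                 clinicalEffects = clinicalEffects,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "psnetSimulationSpec")
}

#' Simulate a two-class cohort with planted pathway signatures
#'
#' Fully seed-deterministic generator; see [simulationSpec()] for the
#' cohort model. Class labels are \code{"case"} (carries the signature)
#' and \code{"control"}.
#'
#' @param spec a [simulationSpec()].
#' @return list with elements \code{expression} ([PatientLayer-class]),
#'   \code{clinical} ([PatientLayer-class] or NULL), \code{labels}
#'   (data.frame id/label), \code{sets} ([GeneSetList-class]) and
#'   \code{truth} (list: \code{predictiveSets}, \code{shift} matrix of
#'   per-gene class-case mean shifts).
#' @export
simulateCohort <- function(spec = simulationSpec()) {
  stopifnot(inherits(spec, "psnetSimulationSpec"))
  .withSeed(spec$seed, {
    n <- 2L * spec$nPerClass
    ids <- sprintf("P%03d", seq_len(n))
    labels <- data.frame(id = ids,
                         label = rep(c("case", "control"),
                                     each = spec$nPerClass),
                         stringsAsFactors = FALSE)
    genes <- sprintf("g%04d", seq_len(spec$nGenes))
    setNames_ <- sprintf("SET%02d", seq_len(spec$nSets))
    members <- lapply(seq_len(spec$nSets), function(k)
      genes[((k - 1L) * spec$setSize + 1L):(k * spec$setSize)])
    names(members) <- setNames_
    sets <- GeneSetList(members,
                        rep("synthetic pathway", spec$nSets))

    expr <- matrix(stats::rnorm(n * spec$nGenes), n, spec$nGenes,
                   dimnames = list(ids, genes))
    shift <- stats::setNames(numeric(spec$nGenes), genes)
    predictive <- setNames_[seq_len(spec$nPredictive)]
    for (ps in predictive) {
      g <- members[[ps]]
      shift[g] <- spec$effectSize * rep_len(c(1, -1), length(g))
    }
    isCase <- labels$label == "case"
    expr[isCase, ] <- expr[isCase, ] +
      matrix(shift, sum(isCase), spec$nGenes, byrow = TRUE)

    clinical <- NULL
    if (spec$nClinicalVars > 0L) {
      eff <- rep_len(spec$clinicalEffects, spec$nClinicalVars)
      cv <- matrix(stats::rnorm(n * spec$nClinicalVars), n,
                   spec$nClinicalVars,
                   dimnames = list(ids,
                                   sprintf("clin%02d",
                                           seq_len(spec$nClinicalVars))))
      cv[isCase, ] <- cv[isCase, ] +
        matrix(eff, sum(isCase), spec$nClinicalVars, byrow = TRUE)
      clinical <- cv
    }

    if (spec$missingRate > 0) {
      expr[stats::runif(length(expr)) < spec$missingRate] <- NA_real_
      if (!is.null(clinical))
        clinical[stats::runif(length(clinical)) < spec$missingRate] <-
          NA_real_
    }

    list(expression = PatientLayer("expression", expr),
         clinical = if (is.null(clinical)) NULL
                    else PatientLayer("clinical", clinical),
         labels = labels, sets = sets,
         truth = list(predictiveSets = predictive, shift = shift))
  })
}

#' Canonical hand-checkable fixtures
#'
#' Small instances used throughout the package's examples and tests:
#' \describe{
#'   \item{\code{"two-cliques-6"}}{6 patients, query \code{p1..p3};
#'     network A joins the two within-group cliques at weight 1, network B
#'     is the complete bipartite query/non-query graph, network C is the
#'     uniform all-ones graph. Only A is informative for the query.}
#'   \item{\code{"wmw-4node"}}{4 patients in two classes; within-class
#'     similarity 0.9, cross-class 0.1 — the worked class-separation
#'     instance (exact one-tailed WMW p = 1/15).}
#'   \item{\code{"separable-120"}}{the default synthetic cohort (60 per
#'     class, 30 sets of 20 genes, 3 predictive, d = 1.5); pass
#'     \code{seed} to vary.}
#'   \item{\code{"null-120"}}{same cohort with effect size 0.}
#' }
#'
#' @param name fixture name.
#' @param seed seed for the simulated fixtures, default 42.
#' @return a list of fixture components (see details).
#' @export
makeFixture <- function(name = c("two-cliques-6", "separable-120",
                                 "null-120", "wmw-4node"), seed = 42L) {
  if (!name[1L] %in% c("two-cliques-6", "separable-120", "null-120",
                       "wmw-4node"))
    stop("unknown fixture '", name[1L], "'; choices: two-cliques-6, ",
         "separable-120, null-120, wmw-4node")
  name <- name[1L]
  if (name == "two-cliques-6") {
    ids <- paste0("p", 1:6)
    clique <- function(members, w = 1) {
      pairs <- t(utils::combn(members, 2L))
      data.frame(from = pairs[, 1L], to = pairs[, 2L], weight = w,
                 stringsAsFactors = FALSE)
    }
    A <- SimilarityNetwork("A", nodes = ids,
                           edges = rbind(clique(ids[1:3]),
                                         clique(ids[4:6])),
                           metricName = "normalized")
    bip <- expand.grid(from = ids[1:3], to = ids[4:6],
                       stringsAsFactors = FALSE)
    bip$weight <- 1
    B <- SimilarityNetwork("B", nodes = ids, edges = bip,
                           metricName = "normalized")
    C <- SimilarityNetwork("C", nodes = ids, edges = clique(ids),
                           metricName = "normalized")
    list(nets = list(A = A, B = B, C = C), query = ids[1:3],
         universe = ids)
  } else if (name == "wmw-4node") {
    ids <- paste0("p", 1:4)
    pairs <- t(utils::combn(ids, 2L))
    e <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                    weight = 0.1, stringsAsFactors = FALSE)
    within <- (e$from == "p1" & e$to == "p2") |
              (e$from == "p3" & e$to == "p4")
    e$weight[within] <- 0.9
    list(net = SimilarityNetwork("wmw", nodes = ids, edges = e,
                                 metricName = "normalized"),
         labels = data.frame(id = ids,
                             label = c("A", "A", "B", "B"),
                             stringsAsFactors = FALSE))
  } else if (name == "separable-120") {
    simulateCohort(simulationSpec(seed = seed))
  } else {
    simulateCohort(simulationSpec(effectSize = 0, seed = seed))
  }
}
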