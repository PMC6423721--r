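test_that("stratified splits preserve class proportions and determinism", {
  labels <- data.frame(id = sprintf("P%03d", 1:100),
                       label = rep(c("x", "y"), each = 50))
  sp <- psnet:::.withSeed(3, stratifiedSplit(labels, 0.8))
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_equal(sum(sp$train %in% labels$id[1:50]), 40L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), labels$id)
  sp2 <- psnet:::.withSeed(3, stratifiedSplit(labels, 0.8))
  expect_identical(sp, sp2)
  tiny <- data.frame(id = c("a", "b", "c", "d", "e"),
                     label = c("x", "x", "x", "y", "y"))
  expect_error(stratifiedSplit(tiny, 0.8), "at least 3")
})

test_that("imputation uses training medians only and drops dead variables", {
  tr <- PatientLayer("l", matrix(c(1, 3, NA, NA, NA, NA, 5, 6, 7), 3, 3,
        dimnames = list(c("a", "b", "c"), c("v1", "v2", "v3"))))
  te <- PatientLayer("l", matrix(c(NA, 10, NA, 2, NA, 4), 2, 3,
        dimnames = list(c("d", "e"), c("v1", "v2", "v3"))))
  expect_warning(out <- imputeMissing(tr, te), "fully missing")
  expect_identical(out$dropped, "v2")
  # train median of v1 over (1, 3) is 2
  expect_equal(unname(layerValues(out$train)["c", "v1"]), 2)
  # test imputed with the training median, not the test median (10)
  expect_equal(unname(layerValues(out$test)["d", "v1"]), 2)
  expect_false(anyNA(layerValues(out$train)))
  expect_false(anyNA(layerValues(out$test)))
})

test_that("lasso prefilter retains a strongly shifted variable, drops pure noise", {
  retainedHit <- 0L
  nullEmptyOrSmall <- 0L
  for (seed in 1:5) {
    n <- 60L
    ids <- sprintf("P%03d", seq_len(n))
    labels <- data.frame(id = ids, label = rep(c("a", "b"), each = n / 2))
    psnet:::.withSeed(400 + seed, {
      m <- matrix(rnorm(n * 31), n,
                  dimnames = list(ids, c("v1", sprintf("n%02d", 1:30))))
      m[labels$label == "a", "v1"] <- m[labels$label == "a", "v1"] + 2
      keep <- lassoPrefilter(PatientLayer("l", m), labels)
      if ("v1" %in% keep) retainedHit <- retainedHit + 1L
      mN <- matrix(rnorm(n * 31), n, dimnames = dimnames(m))
      # glmnet may warn about tiny fold classes on null data; irrelevant here
      keepN <- suppressWarnings(lassoPrefilter(PatientLayer("l", mN),
                                               labels))
      if (length(keepN) <= 3L) nullEmptyOrSmall <- nullEmptyOrSmall + 1L
    })
  }
  expect_equal(retainedHit, 5L)
  expect_gte(nullEmptyOrSmall, 3L)
  # a single perfectly separating variable is retained
  ids <- sprintf("P%02d", 1:20)
  labels <- data.frame(id = ids, label = rep(c("a", "b"), each = 10))
  m <- matrix(c(rep(0, 10), rep(5, 10), rnorm(20)), 20, 2,
              dimnames = list(ids, c("sep", "noise")))
  # 10 per class trips glmnet's small-fold-class warning; harmless here
  keep <- suppressWarnings(
    psnet:::.withSeed(1, lassoPrefilter(PatientLayer("l", m), labels)))
  expect_true("sep" %in% keep)
})

test_that("AUROC/AUPR follow the stated tie conventions and match pROC", {
  # perfect separation
  expect_equal(evaluatePerformance(c(0.9, 0.8, 0.7, 0.1),
                                   c("a", "a", "b", "b"))$auroc, 1)
  # enumerated 4-score example: 3 of 4 positive-negative pairs concordant
  ev <- evaluatePerformance(c(0.9, 0.4, 0.6, 0.2),
                            c("a", "a", "b", "b"))
  expect_equal(ev$auroc, 0.75)
  # all-tied scores give 0.5
  expect_equal(evaluatePerformance(rep(1, 6),
                                   rep(c("a", "b"), 3))$auroc, 0.5)
  expect_error(evaluatePerformance(1:3, c("a", "a", "a")), "single class")
  # agreement with an independent implementation on random scores
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    sc <- round(runif(40), 2)  # rounding forces ties
    tr <- sample(c("a", "b"), 40, replace = TRUE)
    expect_equal(evaluatePerformance(sc, tr)$auroc,
                 as.numeric(suppressMessages(
                   pROC::auc(pROC::roc(tr, sc, levels = c("b", "a"),
                                       direction = "<")))),
                 tolerance = 1e-12)
  }
  # AUPR of perfect ranking is 1; of all-tied scores equals prevalence
  expect_equal(evaluatePerformance(c(0.9, 0.8, 0.2, 0.1),
                                   c("a", "a", "b", "b"))$aupr, 1)
  expect_equal(evaluatePerformance(rep(1, 4),
                                   c("a", "b", "b", "b"))$aupr, 0.25)
})

test_that("classification follows connectivity dominance and the tie contract", {
  ids <- c("tA", "tB", sprintf("a%d", 1:3), sprintf("b%d", 1:3))
  trainLabels <- data.frame(id = c(sprintf("a%d", 1:3), sprintf("b%d", 1:3)),
                            label = rep(c("A", "B"), each = 3))
  # test patient tA connected only to class-A members, tB only to B
  eA <- rbind(data.frame(from = "tA", to = sprintf("a%d", 1:3), weight = 1),
              data.frame(from = "tB", to = sprintf("b%d", 1:3), weight = 1),
              data.frame(from = "a1", to = c("a2", "a3"), weight = 1),
              data.frame(from = "b1", to = c("b2", "b3"), weight = 1))
  net <- SimilarityNetwork("f", nodes = ids, edges = eA,
                           metricName = "normalized")
  dbs <- list(A = list(f = net), B = list(f = net))
  out <- classifyPatients(dbs, trainLabels, c("tA", "tB"))
  expect_identical(out$predicted[out$id == "tA"], "A")
  expect_identical(out$predicted[out$id == "tB"], "B")
  expect_true(all(out$rank_A >= 0 & out$rank_A <= 1))

  # perfectly symmetric patient: identical connectivity to both classes
  # in both databases -> lexicographically smallest class wins
  eS <- rbind(data.frame(from = "tA", to = c(sprintf("a%d", 1:3),
                                             sprintf("b%d", 1:3)),
                         weight = 0.5),
              data.frame(from = "a1", to = c("a2", "a3"), weight = 1),
              data.frame(from = "b1", to = c("b2", "b3"), weight = 1))
  netS <- SimilarityNetwork("f", nodes = setdiff(ids, "tB"), edges = eS,
                            metricName = "normalized")
  dbsS <- list(A = list(f = netS), B = list(f = netS))
  outS <- classifyPatients(dbsS, trainLabels, "tA")
  expect_identical(outS$predicted, "A")
  expect_equal(outS$decision, 0)
})

test_that("the full predictor separates a planted cohort and is reproducible", {
  co <- smallCohort(seed = 500)
  cfg <- predictorConfig(nSplits = 2, nRounds = 6, threshold = 5,
                         seed = 17)
  rep1 <- suppressMessages(suppressWarnings(
    runPredictor(list(expression = co$expression), co$labels, co$sets,
                 cfg)))
  expect_equal(nrow(rep1$metrics), 2L)
  expect_gte(mean(rep1$metrics$auroc), 0.9)
  # byte-identical reproduction from the same master seed
  rep2 <- suppressMessages(suppressWarnings(
    runPredictor(list(expression = co$expression), co$labels, co$sets,
                 cfg)))
  expect_identical(rep1$predictions, rep2$predictions)
  expect_identical(rep1$scoreTables, rep2$scoreTables)
  expect_identical(rep1$metrics, rep2$metrics)
  # single-split run reports exactly one split
  cfg1 <- predictorConfig(nSplits = 1, nRounds = 4, threshold = 3,
                          seed = 17)
  repOne <- suppressMessages(suppressWarnings(
    runPredictor(list(expression = co$expression), co$labels, co$sets,
                 cfg1)))
  expect_equal(nrow(repOne$metrics), 1L)
})

test_that("corrupting the held-out partition never touches feature scores", {
  co <- smallCohort(seed = 501)
  cfg <- predictorConfig(nSplits = 1, nRounds = 5, threshold = 4,
                         seed = 23, impute = TRUE)
  run <- function(exprValues) {
    suppressMessages(suppressWarnings(runPredictor(
      list(expression = PatientLayer("expression", exprValues)),
      co$labels, co$sets, cfg)))
  }
  base <- run(layerValues(co$expression))
  # corrupt the held-out patients' cell values (labels untouched, so the
  # stratified split is unchanged); imputation/classification see these,
  # feature scoring must not
  sp <- psnet:::.withSeed(psnet:::.subSeed(23, "split:1"),
                          stratifiedSplit(co$labels, 0.8))
  v <- layerValues(co$expression)
  v[sp$test, ] <- v[sp$test, ] * 10 + 3
  corrupted <- run(v)
  expect_identical(base$scoreTables, corrupted$scoreTables)
  expect_identical(base$selected, corrupted$selected)

  # with the split held fixed, flipped test labels cannot reach any stage
  # before evaluation: scoring takes training labels, classification takes
  # training labels; recomputing both with a test-label-corrupted table
  # restricted to the training partition is byte-identical
  trainLab <- co$labels[co$labels$id %in% sp$train, ]
  nets <- psnet:::.buildFeatureNetworks(
    list(expression = co$expression), co$sets, cfg, sp$train)
  s1 <- scoreFeatures(nets, sp$train, trainLab,
                      featureSelectionConfig(seed = 9))
  labFlip <- co$labels
  flip <- labFlip$id %in% sp$test
  labFlip$label[flip] <- ifelse(labFlip$label[flip] == "case",
                                "control", "case")
  trainLab2 <- labFlip[labFlip$id %in% sp$train, ]
  s2 <- scoreFeatures(nets, sp$train, trainLab2,
                      featureSelectionConfig(seed = 9))
  expect_identical(s1, s2)
})

test_that("datatype-level mode runs on a clinical-style layer", {
  co <- simulateCohort(simulationSpec(
    nPerClass = 15, nGenes = 40, nSets = 4, setSize = 10,
    nPredictive = 1, effectSize = 2, nClinicalVars = 3,
    clinicalEffects = c(1.5, 0, 0), seed = 77))
  cfg <- predictorConfig(featureMode = "datatype", nSplits = 1,
                         nRounds = 4, threshold = 3, seed = 5)
  rep <- suppressMessages(suppressWarnings(runPredictor(
    list(expression = co$expression, clinical = co$clinical),
    co$labels, NULL, cfg)))
  expect_equal(nrow(rep$metrics), 1L)
  expect_setequal(rownames(rep$scoreTables$split1),
                  c("expression", "clinical"))
})
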