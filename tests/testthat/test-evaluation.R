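test_that("stratified folds partition samples and balance classes", {
  lab <- factor(rep(c("a", "b"), c(26, 10)))
  f <- stratifiedKFold(lab, k = 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  for (k in 1:5)
    expect_true(all(table(lab[f == k]) >= 1))
  perFoldB <- table(f[lab == "b"])
  expect_true(max(perFoldB) - min(perFoldB) <= 1)
  # determinism
  expect_identical(f, stratifiedKFold(lab, k = 5, seed = 1))
  expect_false(identical(f, stratifiedKFold(lab, k = 5, seed = 2)))

  # stratification contract at a feasible k for a 6/4 split
  lab2 <- factor(rep(c("a", "b"), c(6, 4)))
  f2 <- stratifiedKFold(lab2, k = 2, seed = 3)
  for (k in 1:2) expect_true(all(table(lab2[f2 == k]) >= 1))
  # a class smaller than k falls back with a warning
  expect_warning(f3 <- stratifiedKFold(lab2, k = 5, seed = 3),
                 "fewer than k")
  expect_setequal(unique(f3), 1:5)
  expect_error(stratifiedKFold(lab2, k = 11), "exceeds")
})

test_that("AUC equals exhaustive pairwise comparison with ties one half", {
  lab <- factor(c("n", "n", "p", "p"), levels = c("n", "p"))
  expect_equal(aucScore(c(0.1, 0.4, 0.35, 0.8), lab), 0.75)
  expect_equal(aucScore(c(0.1, 0.2, 0.8, 0.9), lab), 1)     # separated
  expect_equal(aucScore(rep(0.5, 4), lab), 0.5)             # all ties
  expect_error(aucScore(1:3, factor(c("p", "p", "p"), levels = c("n", "p"))),
               "classes")

  # symmetry: flipping labels and negating scores preserves AUC
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    y <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    lab <- factor(ifelse(y == 1, "p", "n"), levels = c("n", "p"))
    flip <- factor(ifelse(y == 1, "n", "p"), levels = c("p", "n"))
    expect_equal(aucScore(s, lab), pairwiseAUC(s, y), tolerance = 0)
    expect_equal(aucScore(-s, flip, positive = "p"), aucScore(s, lab))
  }
})

test_that("precision follows TP/(TP+FP) with an explicit undefined sentinel", {
  lab <- factor(c(rep("p", 5), rep("n", 5)), levels = c("n", "p"))
  sc <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.6, 0.55, 0.2, 0.1, 0.05)
  r <- precisionAtThreshold(sc, lab, 0.5)
  expect_identical(unname(r$counts["TP"]), 3L)
  expect_identical(unname(r$counts["FP"]), 2L)
  expect_equal(r$precision, 0.6)
  expect_identical(sum(r$counts), 10L)
  # FP = 0 gives 1; no calls gives NA, never 0
  expect_equal(precisionAtThreshold(sc, lab, 0.65)$precision, 1)
  expect_true(is.na(precisionAtThreshold(sc, lab, 2)$precision))
  # threshold 0 calls everything: precision = prevalence
  expect_equal(precisionAtThreshold(sc, lab, 0)$precision, 0.5)
})

test_that("percent reduction reproduces printed benchmarks and edge cases", {
  expect_equal(round(percentReduction(18756, 3604), 2), 80.78)
  expect_equal(round(percentReduction(819, 114), 2), 86.08)
  expect_equal(percentReduction(10, 10), 0)
  expect_error(percentReduction(0, 0), "positive")
  expect_error(percentReduction(10, 11), "<=")
})

test_that("overlap analysis counts pairwise intersections and recurrence", {
  sets <- list(s1 = c("a", "b", "c"), s2 = c("b", "c"), s3 = "c")
  o <- overlapAnalysis(sets)
  expect_identical(o$recurrent, c("c", "b"))
  expect_identical(unname(o$occurrence[c("c", "b", "a")]), c(3L, 2L, 1L))
  expect_identical(o$pairwise["s1", "s2"], 2L)
  expect_identical(o$pairwise, t(o$pairwise))
  # identical sets: all pairwise counts equal the set size
  oid <- overlapAnalysis(list(x = c("a", "b"), y = c("a", "b")))
  expect_true(all(oid$pairwise == 2L))
  # disjoint sets: no recurrent features
  odis <- overlapAnalysis(list(x = "a", y = "b"))
  expect_length(odis$recurrent, 0L)
  expect_error(overlapAnalysis(list("a")), "at least two")
})

test_that("term coverage is the enriched-term overlap fraction", {
  univ <- paste0("g", 1:30)
  coll <- AnnotationCollection("BP",
    list(T1 = paste0("g", 1:5), T2 = paste0("g", 6:10),
         T3 = paste0("g", 16:20)),
    universe = univ)
  seed <- paste0("g", c(1:5, 6:9))
  # hand enrichment with the brute-force oracle: T1 (n=5, a=5, b=30, d=9)
  # and T2 (n=4) pass alpha = 0.05; T3 (n=0) does not
  expect_equal(bruteHyperTail(5, 30, 9, 5), choose(25, 4) / choose(30, 9),
               tolerance = 1e-12)
  expect_lte(bruteHyperTail(5, 30, 9, 4), 0.05)
  expect_gt(bruteHyperTail(5, 30, 9, 0), 0.05)
  eSeed <- enrichTerms(seed, coll, 0.05)$term
  expect_setequal(eSeed, c("T1", "T2"))
  # a selection enriching T1 only covers half of the seed terms
  expect_equal(termCoverage(paste0("g", 1:5), seed, coll, 0.05), 0.5)
  # identical inputs cover fully; unrelated selection covers nothing
  expect_equal(termCoverage(seed, seed, coll, 0.05), 1)
  expect_equal(termCoverage(paste0("g", 21:25), seed, coll, 0.05), 0)
  # undefined when the seed list enriches no term
  expect_warning(
    cv <- termCoverage(seed, univ, coll, 0.05), "undefined")
  expect_true(is.na(cv))
})

test_that("cross-validation pools each sample exactly once and orders stably", {
  study <- smallStudy(seed = 19, nGenes = 60, nMirnas = 10)
  ds <- buildType2(study@mrna, study@labels)
  cv <- crossValidate(ds, fastSolver(seed = 2), k = 5, seed = 4)
  expect_identical(sum(is.na(cv$pooledScores)), 0L)
  expect_length(cv$pooledScores, ncol(ds))
  expect_setequal(unique(cv$foldAssignments), 1:5)
  expect_true(cv$auc >= 0 && cv$auc <= 1)
  # same seed, same result
  cv2 <- crossValidate(ds, fastSolver(seed = 2), k = 5, seed = 4)
  expect_identical(cv$pooledScores, cv2$pooledScores)
  # sample order invariance given the same fold seed
  perm <- sample(ncol(ds))
  dsPerm <- FilteredDataset(
    SummarizedExperiment::assay(ds)[, perm], sampleLabels(ds)[perm],
    datasetType(ds), datasetVariant(ds), provenance(ds))
  cv3 <- crossValidate(dsPerm, fastSolver(seed = 2), k = 5, seed = 4)
  expect_equal(sort(names(cv3$pooledScores)), sort(names(cv$pooledScores)))
})

test_that("cross-validated AUC is high on signal and null on permuted labels", {
  study <- smallStudy(seed = 29, nGenes = 150, effectSize = 2)
  ds <- buildType2(study@mrna, study@labels)
  cv <- crossValidate(ds, fastSolver(seed = 1), k = 5, seed = 1)
  expect_gte(cv$auc, 0.9)

  nullAucs <- vapply(1:8, function(s) {
    set.seed(3000 + s)
    perm <- setNames(sample(study@labels), names(study@labels))
    dsN <- FilteredDataset(study@mrna[1:40, ], perm, "type1")
    crossValidate(dsN, fastSolver(seed = s), k = 5, seed = s)$auc
  }, 1)
  expect_lt(abs(median(nullAucs) - 0.5), 0.1)
})
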