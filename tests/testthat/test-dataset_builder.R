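test_that("type-1 is the identity filter with order preserved", {
  study <- smallStudy(seed = 2, nGenes = 50, nMirnas = 10)
  t1 <- buildType1(study@mrna, study@labels)
  expect_identical(rownames(t1), rownames(study@mrna))
  expect_identical(provenance(t1)[[1]]$after, 50L)
})

test_that("type-2 equals an independent per-feature t-test oracle", {
  study <- smallStudy(seed = 13, nGenes = 120, nMirnas = 12)
  t2 <- buildType2(study@mrna, study@labels, alphaDe = 0.05)
  oracle <- rownames(study@mrna)[apply(study@mrna, 1, function(v)
    t.test(v[study@labels == "case"],
           v[study@labels == "control"])$p.value <= 0.05)]
  expect_setequal(rownames(t2), oracle)
  # vacuous threshold keeps everything
  expect_identical(rownames(buildType2(study@mrna, study@labels, 1)),
                   rownames(study@mrna))
})

test_that("type-3 mRNA keeps exactly the members of seed-enriched terms", {
  # hand-built 20-gene universe: disease term D = {g1,g2,g3} plus filler
  mat <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("S", 1:8)))
  lab <- factor(rep(c("ctrl", "case"), each = 4), levels = c("ctrl", "case"))
  coll <- AnnotationCollection("BP",
    list(D = c("g1", "g2", "g3"), E = paste0("g", 10:18)),
    universe = rownames(mat))
  # seed list {g1,g2}: for D, p = P(X >= 2 | a=3, b=20, d=2) = 3/C(20,2)
  expect_equal(bruteHyperTail(3, 20, 2, 2), 3 / 190, tolerance = 1e-12)
  t3 <- buildType3Mrna(mat, lab, coll, c("g1", "g2"), alphaEnrich = 0.05)
  expect_setequal(rownames(t3), c("g1", "g2", "g3"))  # exactly D's members

  # seed genes absent from the universe: empty dataset plus warnings
  w <- capture_warnings(t3e <- buildType3Mrna(mat, lab, coll,
                                              c("zz1", "zz2")))
  expect_true(any(grepl("no seed gene", w)))
  expect_identical(nrow(t3e), 0L)
})

test_that("type-4 is the exact intersection of its parents", {
  study <- smallStudy(seed = 23)
  coll <- study@collections$BP
  t2 <- buildType2(study@mrna, study@labels)
  t3 <- buildType3Mrna(study@mrna, study@labels, coll, study@seedGenes)
  t4 <- buildType4Mrna(study@mrna, study@labels, coll, study@seedGenes)
  expect_setequal(rownames(t4), intersect(rownames(t2), rownames(t3)))
  expect_true(all(rownames(t4) %in% rownames(t2)))
  expect_true(all(rownames(t4) %in% rownames(t3)))
  # vacuous DE filter collapses type-4 onto type-3
  t4v <- buildType4Mrna(study@mrna, study@labels, coll, study@seedGenes,
                        alphaDe = 1)
  expect_setequal(rownames(t4v), rownames(t3))
})

test_that("microRNA filters join the target map against the seed list", {
  mat <- matrix(rnorm(3 * 8), 3, 8,
                dimnames = list(c("m1", "m2", "m3"), paste0("S", 1:8)))
  lab <- factor(rep(c("ctrl", "case"), each = 4), levels = c("ctrl", "case"))
  tm <- TargetMap(c("m1", "m2"), c("gA", "gB"))
  t3 <- buildType3Mirna(mat, lab, tm, "gA")
  expect_identical(rownames(t3), "m1")
  # seed covering all targets keeps every microRNA with any pair
  t3all <- buildType3Mirna(mat, lab, tm, c("gA", "gB"))
  expect_setequal(rownames(t3all), c("m1", "m2"))
  # empty map: empty dataset with warning
  expect_warning(
    t3e <- buildType3Mirna(mat, lab, TargetMap(character(), character()),
                           "gA"), "every feature")
  expect_identical(nrow(t3e), 0L)

  # type-4 equals the enumerated intersection of both filters
  study <- smallStudy(seed = 31)
  t2m <- buildType2(study@mirna, study@labels)
  t3m <- buildType3Mirna(study@mirna, study@labels, study@targetMap,
                         study@seedGenes)
  t4m <- buildType4Mirna(study@mirna, study@labels, study@targetMap,
                         study@seedGenes)
  pairs <- targetPairs(study@targetMap)
  oracle <- intersect(
    rownames(study@mirna)[rowTTest(study@mirna, study@labels)$p.value <= 0.05],
    unique(pairs$mirna[pairs$gene %in% study@seedGenes]))
  expect_setequal(rownames(t4m), oracle)
  expect_setequal(rownames(t4m), intersect(rownames(t2m), rownames(t3m)))
})

test_that("buildAll emits 14 datasets with the subset laws holding", {
  study <- smallStudy(seed = 41)
  ds <- suppressWarnings(buildAll(study = study))
  expect_length(ds, 14L)
  expect_identical(names(ds)[1:2], c("mrna.type1", "mrna.type2"))
  t1g <- rownames(ds$mrna.type1)
  for (nm in grep("^mrna", names(ds), value = TRUE))
    expect_true(all(rownames(ds[[nm]]) %in% t1g))
  for (v in c("BP", "MF", "CC", "Pathway"))
    expect_setequal(rownames(ds[[paste0("mrna.type4.", v)]]),
                    intersect(rownames(ds$mrna.type2),
                              rownames(ds[[paste0("mrna.type3.", v)]])))
  t1m <- rownames(ds$mirna.type1)
  for (nm in grep("^mirna", names(ds), value = TRUE))
    expect_true(all(rownames(ds[[nm]]) %in% t1m))
})

test_that("raising thresholds never shrinks the filtered sets", {
  study <- smallStudy(seed = 8, nGenes = 200)
  sizes2 <- vapply(c(0.01, 0.05, 0.2, 1), function(a)
    nrow(buildType2(study@mrna, study@labels, a)), 1L)
  expect_true(all(diff(sizes2) >= 0L))
  sizes3 <- vapply(c(0.001, 0.05, 0.5, 1), function(a)
    nrow(suppressWarnings(buildType3Mrna(study@mrna, study@labels,
      study@collections$BP, study@seedGenes, a))), 1L)
  expect_true(all(diff(sizes3) >= 0L))
})

test_that("type-4-BP recovers planted disease genes under strong signal", {
  study <- smallStudy(seed = 55, effectSize = 1.5, seedEnrichmentBias = 0.9)
  t4 <- buildType4Mrna(study@mrna, study@labels, study@collections$BP,
                       study@seedGenes)
  diseaseMembers <- unique(unlist(
    geneSets(study@collections$BP)[study@truth$diseaseTerms$BP],
    use.names = FALSE))
  targets <- intersect(study@truth$deGenes, diseaseMembers)
  expect_gte(length(targets), 5L)
  expect_gte(mean(targets %in% rownames(t4)), 0.8)
})
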