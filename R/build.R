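# Construction of the four pre-filtered dataset types per expression layer:
#   type1  raw features
#   type2  differentially expressed features (t-test, p <= alphaDe)
#   type3  disease-knowledge features (term enrichment of the seed list for
#          mRNA; seed-gene targeting for microRNA)
#   type4  intersection of type2 and type3
# For mRNA, types 3 and 4 come in one variant per term collection
# (BP/MF/CC/Pathway), giving 10 mRNA datasets; the microRNA layer has one
# dataset per type, giving 4 — 14 in total.

provRecord <- function(description, before, after) {
  list(description = description, before = as.integer(before),
       after = as.integer(after))
}

subsetDataset <- function(mat, labels, keep, datasetType, variant,
                          provenance) {
  ds <- FilteredDataset(mat[keep, , drop = FALSE], labels, datasetType,
                        variant, provenance)
  if (nrow(ds) == 0L)
    warning(datasetType,
            if (!is.na(variant)) paste0("-", variant) else "",
            " filter removed every feature; downstream stages must skip ",
            "this dataset explicitly")
  ds
}

#' Build the Type-1 (raw) dataset
#'
#' Identity filter: all measured features, order preserved. Provenance
#' records the raw feature count.
#'
#' @param mat expression matrix, features x samples.
#' @param labels two-class factor over the samples (named, or in column
#'   order).
#' @return A [FilteredDataset-class] of type `type1`.
#' @export
buildType1 <- function(mat, labels) {
  FilteredDataset(mat, labels, "type1",
                  provenance = list(provRecord("raw features", nrow(mat),
                                               nrow(mat))))
}

#' Build the Type-2 (differential expression) dataset
#'
#' Keeps features whose two-sample t-test p-value is at most `alphaDe`
#' (inclusive threshold).
#'
#' @inheritParams buildType1
#' @param alphaDe t-test threshold, default 0.05.
#' @param positive positive-class label (defaults to second factor level).
#' @param varEqual use Student's pooled test instead of Welch.
#' @return A [FilteredDataset-class] of type `type2`.
#' @export
buildType2 <- function(mat, labels, alphaDe = 0.05, positive = NULL,
                       varEqual = FALSE) {
  stopifnot(alphaDe > 0, alphaDe <= 1)
  tt <- rowTTest(mat, labels, positive = positive, varEqual = varEqual)
  keep <- tt$p.value <= alphaDe
  subsetDataset(mat, labels, keep, "type2", NA_character_, list(provRecord(
    sprintf("%s t-test p <= %g", if (varEqual) "Student" else "Welch",
            alphaDe), nrow(mat), sum(keep))))
}

#' Build a Type-3 mRNA dataset from one term collection
#'
#' Enriches the disease seed-gene list against the collection (restricted
#' to the measured features) and keeps every measured feature annotated to
#' at least one enriched term.
#'
#' @inheritParams buildType2
#' @param coll an [AnnotationCollection]; it is restricted to the measured
#'   features internally.
#' @param seedGenes disease seed-gene identifiers.
#' @param alphaEnrich enrichment threshold, default 0.05.
#' @return A [FilteredDataset-class] of type `type3` tagged with the
#'   collection name.
#' @export
buildType3Mrna <- function(mat, labels, coll, seedGenes, alphaEnrich = 0.05) {
  stopifnot(alphaEnrich > 0, alphaEnrich <= 1)
  coll <- restrictToUniverse(coll, rownames(mat))
  seedIn <- intersect(seedGenes, universe(coll))
  if (!length(seedIn)) {
    warning("no seed gene occurs among the measured features; ",
            "type3-", collectionName(coll), " is empty")
    enriched <- character()
  } else {
    enr <- suppressWarnings(enrichTerms(seedIn, coll, alpha = alphaEnrich))
    enriched <- enr$term
  }
  members <- unique(unlist(geneSets(coll)[enriched], use.names = FALSE))
  keep <- rownames(mat) %in% members
  subsetDataset(mat, labels, keep, "type3", collectionName(coll),
                list(provRecord(
    sprintf("members of %d term(s) of %s enriched in %d seed genes at p <= %g",
            length(enriched), collectionName(coll), length(seedIn),
            alphaEnrich), nrow(mat), sum(keep))))
}

#' Build a Type-4 mRNA dataset (differential AND disease-annotated)
#'
#' Feature set is the exact intersection of the Type-2 and Type-3 sets
#' built at the same thresholds; provenance chains both filters.
#'
#' @inheritParams buildType3Mrna
#' @param alphaDe t-test threshold.
#' @return A [FilteredDataset-class] of type `type4` tagged with the
#'   collection name.
#' @export
buildType4Mrna <- function(mat, labels, coll, seedGenes, alphaDe = 0.05,
                           alphaEnrich = 0.05, positive = NULL,
                           varEqual = FALSE) {
  t2 <- suppressWarnings(buildType2(mat, labels, alphaDe, positive, varEqual))
  t3 <- suppressWarnings(buildType3Mrna(mat, labels, coll, seedGenes,
                                        alphaEnrich))
  keep <- rownames(mat) %in% intersect(rownames(t2), rownames(t3))
  subsetDataset(mat, labels, keep, "type4", datasetVariant(t3),
                c(provenance(t2), provenance(t3),
                  list(provRecord("intersection of type2 and type3",
                                  nrow(mat), sum(keep)))))
}

#' Build the Type-3 microRNA dataset (seed-gene targeting)
#'
#' Keeps microRNAs with at least one validated target among the disease
#' seed genes.
#'
#' @inheritParams buildType1
#' @param targetMap a [TargetMap] of validated microRNA-gene pairs.
#' @param seedGenes disease seed-gene identifiers.
#' @return A [FilteredDataset-class] of type `type3`.
#' @export
buildType3Mirna <- function(mat, labels, targetMap, seedGenes) {
  pairs <- targetPairs(targetMap)
  targeting <- unique(pairs$mirna[pairs$gene %in% seedGenes])
  keep <- rownames(mat) %in% targeting
  subsetDataset(mat, labels, keep, "type3", NA_character_, list(provRecord(
    sprintf("microRNAs targeting >= 1 of %d seed genes (%d validated pairs)",
            length(unique(seedGenes)), nrow(pairs)), nrow(mat), sum(keep))))
}

#' Build the Type-4 microRNA dataset (differential AND seed-targeting)
#'
#' Intersection of the Type-2 and Type-3 microRNA sets.
#'
#' @inheritParams buildType3Mirna
#' @inheritParams buildType2
#' @return A [FilteredDataset-class] of type `type4`.
#' @export
buildType4Mirna <- function(mat, labels, targetMap, seedGenes,
                            alphaDe = 0.05, positive = NULL,
                            varEqual = FALSE) {
  t2 <- suppressWarnings(buildType2(mat, labels, alphaDe, positive, varEqual))
  t3 <- suppressWarnings(buildType3Mirna(mat, labels, targetMap, seedGenes))
  keep <- rownames(mat) %in% intersect(rownames(t2), rownames(t3))
  subsetDataset(mat, labels, keep, "type4", NA_character_,
                c(provenance(t2), provenance(t3),
                  list(provRecord("intersection of type2 and type3",
                                  nrow(mat), sum(keep)))))
}

#' Build all 14 pre-filtered datasets of a paired study
#'
#' Produces, in fixed order, the mRNA datasets type1, type2,
#' type3-\{BP, MF, CC, Pathway\}, type4-\{BP, MF, CC, Pathway\} and the
#' microRNA datasets type1-type4. Accepts either a
#' [SyntheticStudy-class] or the individual components.
#'
#' @param mrna,mirna expression matrices (features x samples), or pass
#'   `study`.
#' @param labels shared two-class factor over the samples.
#' @param collections named list of [AnnotationCollection] objects (the
#'   names become the type3/type4 variants).
#' @param seedGenes disease seed-gene identifiers.
#' @param targetMap a [TargetMap].
#' @param study optional [SyntheticStudy-class] supplying all components.
#' @param alphaDe,alphaEnrich filter thresholds (default 0.05, inclusive).
#' @param positive positive-class label.
#' @param varEqual use Student's pooled t-test.
#' @return Named list of 14 [FilteredDataset-class] objects, e.g.
#'   `mrna.type3.BP`, `mirna.type2`.
#' @examples
#' study <- simulateStudy(simulationConfig(nGenes = 100, nMirnas = 20,
#'   nPos = 10, nNeg = 10, nTargetPairs = 60))
#' ds <- buildAll(study = study)
#' names(ds)
#' @export
buildAll <- function(mrna = NULL, mirna = NULL, labels = NULL,
                     collections = NULL, seedGenes = NULL, targetMap = NULL,
                     study = NULL, alphaDe = 0.05, alphaEnrich = 0.05,
                     positive = NULL, varEqual = FALSE) {
  if (!is.null(study)) {
    stopifnot(is(study, "SyntheticStudy"))
    mrna <- study@mrna; mirna <- study@mirna; labels <- study@labels
    collections <- study@collections; seedGenes <- study@seedGenes
    targetMap <- study@targetMap
  }
  stopifnot(is.matrix(mrna), is.matrix(mirna), !is.null(collections),
            !is.null(seedGenes), is(targetMap, "TargetMap"))
  out <- list(
    mrna.type1 = buildType1(mrna, labels),
    mrna.type2 = buildType2(mrna, labels, alphaDe, positive, varEqual))
  for (nm in names(collections)) {
    out[[paste0("mrna.type3.", nm)]] <-
      buildType3Mrna(mrna, labels, collections[[nm]], seedGenes, alphaEnrich)
  }
  for (nm in names(collections)) {
    out[[paste0("mrna.type4.", nm)]] <-
      buildType4Mrna(mrna, labels, collections[[nm]], seedGenes, alphaDe,
                     alphaEnrich, positive, varEqual)
  }
  out$mirna.type1 <- buildType1(mirna, labels)
  out$mirna.type2 <- buildType2(mirna, labels, alphaDe, positive, varEqual)
  out$mirna.type3 <- buildType3Mirna(mirna, labels, targetMap, seedGenes)
  out$mirna.type4 <- buildType4Mirna(mirna, labels, targetMap, seedGenes,
                                     alphaDe, positive, varEqual)
  out
}
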