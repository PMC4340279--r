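#' Named gene-set collection with an explicit background universe
#'
#' Holds one collection of functional terms (GO biological process,
#' molecular function, cellular component, or pathways), each term a set of
#' feature identifiers, together with the background universe against which
#' hypergeometric enrichment is computed. The universe defaults to the union
#' of all members at construction and is fixed explicitly with
#' [restrictToUniverse()] before testing, so that the background of the
#' enrichment test is never implicit.
#'
#' @slot collectionName single string naming the collection (e.g. "BP").
#' @slot geneSets named list; each element a character vector of member
#'   feature identifiers.
#' @slot universe character vector of background feature identifiers.
#'
#' @seealso [readGeneSets()], [restrictToUniverse()], [enrichTerms()]
#' @export
setClass("AnnotationCollection",
  slots = c(collectionName = "character",
            geneSets = "list",
            universe = "character"))

setValidity("AnnotationCollection", function(object) {
  msg <- character()
  if (length(object@collectionName) != 1L)
    msg <- c(msg, "collectionName must be a single string")
  sets <- object@geneSets
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == ""))
      msg <- c(msg, "geneSets must be uniquely named")
    if (any(vapply(sets, length, 1L) == 0L))
      msg <- c(msg, "geneSets must not contain empty terms")
    if (!all(vapply(sets, is.character, TRUE)))
      msg <- c(msg, "geneSets members must be character vectors")
  }
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' @rdname AnnotationCollection-class
#' @param collectionName collection label.
#' @param geneSets named list of character vectors (term -> members).
#' @param universe background identifiers; defaults to the union of all
#'   term members.
#' @return An `AnnotationCollection` object.
#' @export
AnnotationCollection <- function(collectionName, geneSets, universe = NULL) {
  geneSets <- lapply(geneSets, function(g) unique(as.character(g)))
  if (is.null(universe)) universe <- unique(unlist(geneSets, use.names = FALSE))
  if (is.null(universe)) universe <- character()
  new("AnnotationCollection", collectionName = as.character(collectionName),
      geneSets = geneSets, universe = as.character(universe))
}

#' Validated microRNA-to-gene target relation
#'
#' A many-to-many set of (microRNA, gene) pairs emulating validated
#' interaction records (miRTarBase-style). Duplicate pairs are collapsed at
#' construction.
#'
#' @slot pairs data.frame with character columns `mirna` and `gene`, one row
#'   per unique validated pair.
#' @seealso [readTargetMap()], [buildType3Mirna()]
#' @export
setClass("TargetMap", slots = c(pairs = "data.frame"))

setValidity("TargetMap", function(object) {
  p <- object@pairs
  msg <- character()
  if (!identical(colnames(p), c("mirna", "gene")))
    msg <- c(msg, "pairs must have columns 'mirna' and 'gene'")
  else {
    if (!is.character(p$mirna) || !is.character(p$gene))
      msg <- c(msg, "pair columns must be character")
    else if (nrow(p) && (any(!nzchar(p$mirna)) || any(!nzchar(p$gene))))
      msg <- c(msg, "identifiers must be non-empty strings")
    if (anyDuplicated(p))
      msg <- c(msg, "duplicate pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TargetMap-class
#' @param mirna character vector of microRNA identifiers (or a two-column
#'   data.frame when `gene` is missing).
#' @param gene character vector of target gene identifiers.
#' @return A `TargetMap` object.
#' @export
TargetMap <- function(mirna, gene = NULL) {
  if (is.data.frame(mirna) && is.null(gene)) {
    df <- data.frame(mirna = as.character(mirna[[1L]]),
                     gene = as.character(mirna[[2L]]),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(mirna = as.character(mirna), gene = as.character(gene),
                     stringsAsFactors = FALSE)
  }
  df <- unique(df)
  rownames(df) <- NULL
  new("TargetMap", pairs = df)
}

#' Pre-filtered expression dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] (assay `expr`, features in
#' rows, samples in columns, binary class label in `colData(x)$label`)
#' restricted to the features surviving one of the four pre-filter types,
#' tagged with its type, optional collection variant, and a provenance trail
#' recording each filter applied (test, threshold, before/after counts).
#'
#' Types: `type1` raw features; `type2` differentially expressed features
#' (two-sample t-test, p <= alpha); `type3` disease-knowledge features
#' (members of terms enriched in the seed-gene list, or microRNAs targeting
#' a seed gene); `type4` the intersection of type2 and type3.
#'
#' @slot datasetType one of `"type1"`, `"type2"`, `"type3"`, `"type4"`.
#' @slot variant collection tag (`"BP"`, `"MF"`, `"CC"`, `"Pathway"`) for
#'   mRNA types 3-4, otherwise `NA`.
#' @slot provenance list of filter-description records.
#' @seealso [buildAll()], [selectFeatures()], [crossValidate()]
#' @export
setClass("FilteredDataset",
  contains = "SummarizedExperiment",
  slots = c(datasetType = "character",
            variant = "character",
            provenance = "list"))

setValidity("FilteredDataset", function(object) {
  msg <- character()
  if (!object@datasetType %in% c("type1", "type2", "type3", "type4"))
    msg <- c(msg, "datasetType must be one of type1..type4")
  if (length(object@variant) != 1L)
    msg <- c(msg, "variant must be length 1 (possibly NA)")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  if (object@datasetType != "type1" && length(object@provenance) == 0L)
    msg <- c(msg, "provenance must be non-empty for types 2-4")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature identifiers")
  if (length(msg)) msg else TRUE
})

#' @rdname FilteredDataset-class
#' @param mat numeric matrix, features x samples, with dimnames.
#' @param labels named factor (or coercible) of per-sample class labels;
#'   names must cover `colnames(mat)`.
#' @param datasetType dataset type tag.
#' @param variant optional collection tag.
#' @param provenance list of filter records.
#' @return A `FilteredDataset` object.
#' @export
FilteredDataset <- function(mat, labels, datasetType, variant = NA_character_,
                            provenance = list()) {
  labels <- as.factor(labels)
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(mat), names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(head(missing, 5), collapse = ", "))
    labels <- labels[colnames(mat)]
  } else if (length(labels) != ncol(mat)) {
    stop("labels length does not match number of samples")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(label = labels, row.names = colnames(mat)))
  new("FilteredDataset", se, datasetType = datasetType,
      variant = as.character(variant), provenance = provenance)
}

#' Result of one L1 logistic-regression feature selection
#'
#' The nonzero-coefficient feature set from a full-data L1 logistic fit on
#' one pre-filtered dataset, with the coefficients on the original feature
#' scale, the penalty used, and fit diagnostics.
#'
#' @slot datasetType,variant tags copied from the input dataset.
#' @slot selected character vector of selected feature identifiers.
#' @slot coefficients named numeric vector of the matching nonzero weights.
#' @slot lambda penalty at which the reported fit was obtained.
#' @slot fit list of diagnostics (`objective`, `converged`, `nIter`,
#'   `kkt`, `intercept`, `lambdaMax`, optional `cvLogLoss`).
#' @seealso [selectFeatures()], [overlapAnalysis()]
#' @export
setClass("SelectionResult",
  slots = c(datasetType = "character", variant = "character",
            selected = "character", coefficients = "numeric",
            lambda = "numeric", fit = "list"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@selected) != length(object@coefficients))
    msg <- c(msg, "selected and coefficients must have equal length")
  if (length(object@coefficients) && any(object@coefficients == 0))
    msg <- c(msg, "coefficients must all be nonzero")
  if (length(msg)) msg else TRUE
})

#' Synthetic paired two-class mRNA/microRNA study
#'
#' Container for one simulated study: paired expression matrices, shared
#' sample labels, term collections, a disease seed-gene list, a validated
#' target map, the generating configuration, and a truth record of all
#' planted structure (differential genes/microRNAs, disease terms).
#'
#' @slot mrna,mirna numeric matrices, features x samples (log-intensity
#'   scale), sharing column (sample) identifiers.
#' @slot labels named factor, levels `control` < `case`; `case` is the
#'   positive (disease) class.
#' @slot collections named list of [AnnotationCollection] objects.
#' @slot seedGenes character vector of disease seed-gene identifiers.
#' @slot targetMap [TargetMap] of validated microRNA-gene pairs.
#' @slot truth list: `deGenes`, `deMirnas`, `diseaseTerms` (named by
#'   collection).
#' @slot config the generating configuration (see [simulationConfig()]).
#' @seealso [simulateStudy()], [writeStudy()]
#' @export
setClass("SyntheticStudy",
  slots = c(mrna = "matrix", mirna = "matrix", labels = "factor",
            collections = "list", seedGenes = "character",
            targetMap = "TargetMap", truth = "list", config = "list"))

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  if (!identical(colnames(object@mrna), colnames(object@mirna)))
    msg <- c(msg, "mrna and mirna must share sample identifiers (paired design)")
  if (!identical(sort(names(object@labels)), sort(colnames(object@mrna))))
    msg <- c(msg, "labels must cover every sample of both matrices")
  if (!all(object@truth$deGenes %in% rownames(object@mrna)))
    msg <- c(msg, "truth deGenes must be a subset of mrna features")
  if (!all(object@truth$deMirnas %in% rownames(object@mirna)))
    msg <- c(msg, "truth deMirnas must be a subset of mirna features")
  if (!all(object@seedGenes %in% rownames(object@mrna)))
    msg <- c(msg, "seedGenes must be a subset of mrna features")
  if (length(msg)) msg else TRUE
})
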