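#' @describeIn AnnotationCollection-class collection label accessor.
#' @param x an object.
#' @export
setGeneric("collectionName", function(x) standardGeneric("collectionName"))

#' @describeIn AnnotationCollection-class named list of term member sets.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @describeIn AnnotationCollection-class background universe accessor.
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @describeIn TargetMap-class the (mirna, gene) pair table.
#' @export
setGeneric("targetPairs", function(x) standardGeneric("targetPairs"))

#' @describeIn FilteredDataset-class dataset type tag accessor.
#' @export
setGeneric("datasetType", function(x) standardGeneric("datasetType"))

#' @describeIn FilteredDataset-class collection variant accessor.
#' @export
setGeneric("datasetVariant", function(x) standardGeneric("datasetVariant"))

#' @describeIn FilteredDataset-class provenance trail accessor.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn SelectionResult-class selected feature identifiers.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @export
setMethod("collectionName", "AnnotationCollection", function(x) x@collectionName)

#' @export
setMethod("geneSets", "AnnotationCollection", function(x) x@geneSets)

#' @export
setMethod("universe", "AnnotationCollection", function(x) x@universe)

#' @export
setMethod("targetPairs", "TargetMap", function(x) x@pairs)

#' @export
setMethod("datasetType", "FilteredDataset", function(x) x@datasetType)

#' @export
setMethod("datasetVariant", "FilteredDataset", function(x) x@variant)

#' @export
setMethod("provenance", "FilteredDataset", function(x) x@provenance)

#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' Per-sample class labels of a dataset
#'
#' @param x a [FilteredDataset].
#' @return Named factor of class labels, one per sample/column.
#' @export
sampleLabels <- function(x) {
  stopifnot(is(x, "FilteredDataset"))
  lab <- SummarizedExperiment::colData(x)$label
  setNames(lab, colnames(x))
}

#' Coefficients of a selection result
#'
#' @param object a [SelectionResult].
#' @param ... ignored.
#' @return Named numeric vector of nonzero coefficients on the original
#'   feature scale.
#' @export
setMethod("coef", "SelectionResult", function(object, ...) object@coefficients)

setMethod("show", "AnnotationCollection", function(object) {
  cat("AnnotationCollection '", object@collectionName, "': ",
      length(object@geneSets), " terms, universe of ",
      length(object@universe), " features\n", sep = "")
  if (length(object@geneSets)) {
    sz <- vapply(object@geneSets, length, 1L)
    cat("  term sizes: min ", min(sz), ", median ", stats::median(sz),
        ", max ", max(sz), "\n", sep = "")
  }
})

setMethod("show", "TargetMap", function(object) {
  cat("TargetMap: ", nrow(object@pairs), " validated pairs, ",
      length(unique(object@pairs$mirna)), " microRNAs, ",
      length(unique(object@pairs$gene)), " target genes\n", sep = "")
})

setMethod("show", "FilteredDataset", function(object) {
  v <- if (is.na(object@variant)) "" else paste0("-", object@variant)
  cat("FilteredDataset ", object@datasetType, v, ": ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  lab <- SummarizedExperiment::colData(object)$label
  cat("  classes: ", paste(sprintf("%s=%d", names(table(lab)), table(lab)),
                           collapse = ", "), "\n", sep = "")
  for (p in object@provenance)
    cat("  filter: ", p$description, " (", p$before, " -> ", p$after, ")\n",
        sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  v <- if (is.na(object@variant)) "" else paste0("-", object@variant)
  cat("SelectionResult for ", object@datasetType, v, ": ",
      length(object@selected), " features at lambda = ",
      signif(object@lambda, 4), "\n", sep = "")
  if (isFALSE(object@fit$converged))
    cat("  warning: fit did not converge\n")
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy: ", nrow(object@mrna), " genes, ", nrow(object@mirna),
      " microRNAs, ", ncol(object@mrna), " paired samples\n", sep = "")
  cat("  classes: ", paste(sprintf("%s=%d", names(table(object@labels)),
                                   table(object@labels)), collapse = ", "),
      "\n  collections: ", paste(names(object@collections), collapse = ", "),
      "\n  seed genes: ", length(object@seedGenes),
      "; target pairs: ", nrow(object@targetMap@pairs),
      "\n  planted: ", length(object@truth$deGenes), " DE genes, ",
      length(object@truth$deMirnas), " DE microRNAs\n", sep = "")
})
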