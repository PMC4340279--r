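# Readers and writers for every on-disk artifact the pipeline touches.
# Expression: TSV, header row = sample IDs, first column = feature IDs.
# Gene sets: GMT. Target map / probe map: headerless two-column TSV.
# Labels: two-column TSV. Seed genes: one ID per line.

#' Read a feature-by-sample expression matrix from TSV
#'
#' The expected layout is a tab-separated table whose header row holds the
#' sample identifiers and whose first column holds the feature identifiers;
#' the body is numeric (log-scale expression). Row and column order are
#' preserved. Identifiers are treated as opaque case-sensitive strings.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix with feature identifiers as rownames and sample
#'   identifiers as colnames; all entries finite.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(matrix(1:6 / 2, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("S1", "S2"))), tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sampleIds <- header[-1L]
  if (!length(sampleIds)) stop("no sample columns in header of ", path)
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifier(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  body <- lines[-1L]
  if (!length(body)) stop("no feature rows in ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(sampleIds) + 1L)
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, " of ", path,
         " (expected ", length(sampleIds) + 1L, " fields, found ",
         nf[bad[1L]], ")")
  featureIds <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(featureIds))
    stop("duplicate feature identifier(s): ",
         paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(length(sampleIds))))
  vals <- if (length(sampleIds) == 1L) matrix(vals, nrow = 1L) else vals
  m <- t(matrix(vals, nrow = length(sampleIds)))
  nonFinite <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(nonFinite))
    stop("non-numeric or non-finite cell at line ",
         nonFinite[1L, 1L] + 1L, " of ", path)
  dimnames(m) <- list(featureIds, sampleIds)
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written in fixed notation with 6 significant digits; the
#' formatting is part of the on-disk contract so that a write/read
#' round-trip reproduces values exactly as written.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- apply(mat, 1L, function(r)
    paste(formatC(signif(r, 6), format = "fg", digits = 6, flag = "#"),
          collapse = "\t"))
  # formatC("fg") can leave a trailing "."; strip it for clean cells
  body <- gsub("\\.\t", "\t", paste0(body, "\t"))
  body <- sub("\t$", "", body)
  lines <- c(paste(c("feature", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample class labels from a two-column TSV
#'
#' @param path headerless two-column TSV: sample identifier, label.
#' @param positive optional label value to treat as the positive (disease)
#'   class; it becomes the second factor level. Defaults to the
#'   lexicographically larger label.
#' @return Named factor with exactly two levels.
#' @export
readSampleLabels <- function(path, positive = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                   quote = "", comment.char = "")
  if (ncol(df) != 2L) stop("labels file must have exactly two columns")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample identifiers in ", path)
  vals <- unique(df[[2L]])
  if (length(vals) != 2L)
    stop("expected exactly two distinct labels, found ", length(vals))
  if (is.null(positive)) positive <- sort(vals)[2L]
  if (!positive %in% vals) stop("positive label '", positive, "' not present")
  lev <- c(setdiff(vals, positive), positive)
  setNames(factor(df[[2L]], levels = lev), df[[1L]])
}

#' @rdname readSampleLabels
#' @param labels named factor of labels.
#' @export
writeSampleLabels <- function(labels, path) {
  write.table(data.frame(names(labels), as.character(labels)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated fields `term`,
#' `description`, then one or more member identifiers. The universe of the
#' returned collection is the union of all members; fix it explicitly with
#' [restrictToUniverse()] before enrichment so the test background is the
#' set of features actually measured.
#'
#' @param path path to the GMT file.
#' @param collectionName label for the collection; defaults to the file
#'   name without extension.
#' @return An [AnnotationCollection].
#' @export
readGeneSets <- function(path, collectionName = NULL) {
  if (is.null(collectionName))
    collectionName <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(AnnotationCollection(collectionName, list(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate term identifiers in ", path)
  AnnotationCollection(collectionName, sets)
}

#' @rdname readGeneSets
#' @param coll an [AnnotationCollection] to write.
#' @export
writeGeneSets <- function(coll, path) {
  lines <- vapply(names(geneSets(coll)), function(tm)
    paste(c(tm, "na", geneSets(coll)[[tm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to an explicit background universe
#'
#' Intersects every term with `universe`, drops terms emptied by the
#' intersection, and records `universe` as the collection background. This
#' makes the `b` (total genes) of the hypergeometric enrichment test an
#' explicit choice rather than an artifact of the annotation file.
#' Idempotent for a fixed universe.
#'
#' @param coll an [AnnotationCollection].
#' @param universe non-empty character vector of background identifiers.
#' @return The restricted [AnnotationCollection].
#' @export
restrictToUniverse <- function(coll, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  sets <- lapply(geneSets(coll), intersect, y = universe)
  sets <- sets[lengths(sets) > 0L]
  AnnotationCollection(collectionName(coll), sets, universe)
}

#' Read a microRNA-target map from a two-column TSV
#'
#' @param path headerless TSV: microRNA identifier, target gene identifier.
#'   Duplicate pairs are collapsed.
#' @return A [TargetMap].
#' @export
readTargetMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                   quote = "", comment.char = "")
  if (ncol(df) != 2L) stop("target map must have exactly two columns")
  TargetMap(df[[1L]], df[[2L]])
}

#' @rdname readTargetMap
#' @param map a [TargetMap] to write.
#' @export
writeTargetMap <- function(map, path) {
  write.table(targetPairs(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a seed-gene list (one identifier per line)
#'
#' @param path text file, one feature identifier per line.
#' @return Character vector of unique identifiers.
#' @export
readSeedGenes <- function(path) {
  ids <- readLines(path)
  unique(ids[nzchar(ids)])
}

#' @rdname readSeedGenes
#' @param genes character vector to write.
#' @export
writeSeedGenes <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Collapse probe-level rows to feature-level rows
#'
#' Microarray expression arrives per probe; multiple probes may interrogate
#' the same gene. Mapped probes are collapsed to one row per feature by the
#' per-sample mean (or median) across the feature's probes; unmapped probes
#' are dropped. A probe mapping to more than one feature is refused as
#' ambiguous. The collapse is recorded in the `collapse` attribute of the
#' result (probe and feature counts, rule used).
#'
#' @param mat probe-level expression matrix (probes x samples).
#' @param mapping two-column data.frame (probe, feature) or named character
#'   vector `probe -> feature`. Probe identifiers must occur in
#'   `rownames(mat)`.
#' @param method collapse rule, `"mean"` (default) or `"median"`.
#' @return Feature-level matrix, one row per mapped feature, in order of
#'   first appearance in `mapping`.
#' @export
collapseProbes <- function(mat, mapping, method = c("mean", "median")) {
  method <- match.arg(method)
  if (is.data.frame(mapping)) {
    probes <- as.character(mapping[[1L]]); feats <- as.character(mapping[[2L]])
  } else {
    probes <- names(mapping); feats <- as.character(mapping)
  }
  keep <- !duplicated(paste0(probes, "\r", feats))
  probes <- probes[keep]; feats <- feats[keep]
  if (anyDuplicated(probes)) {
    amb <- unique(probes[duplicated(probes)])
    stop("ambiguous mapping: probe(s) ", paste(head(amb, 5), collapse = ", "),
         " map to more than one feature")
  }
  missing <- setdiff(probes, rownames(mat))
  if (length(missing))
    stop("mapping references unknown probe(s): ",
         paste(head(missing, 5), collapse = ", "))
  outFeats <- unique(feats)
  fun <- if (method == "mean") colMeans else
    function(x) apply(x, 2L, stats::median)
  out <- t(vapply(outFeats, function(f) {
    rows <- probes[feats == f]
    if (length(rows) == 1L) mat[rows, ] else fun(mat[rows, , drop = FALSE])
  }, numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  attr(out, "collapse") <- list(rule = method, probesIn = nrow(mat),
                                probesMapped = length(probes),
                                featuresOut = length(outFeats))
  out
}
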