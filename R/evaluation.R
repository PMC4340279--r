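# Evaluation of the pre-filter / selection pipeline: stratified k-fold
# cross-validation with pooled held-out scores, rank-based AUC (ties count
# one half), precision at a probability threshold, percent feature
# reduction, cross-dataset overlap, and enriched-term coverage.

#' Stratified k-fold assignment
#'
#' Each class is shuffled and dealt round-robin across folds with a single
#' continuing counter, so total fold sizes differ by at most one and each
#' class's per-fold counts differ by at most one. With fewer than `k`
#' members in some class, stratification is impossible and the function
#' falls back to a plain shuffled split with a warning. Deterministic
#' given `seed`.
#'
#' @param labels factor of class labels (named or positional).
#' @param k number of folds (>= 2, <= number of samples).
#' @param seed integer seed.
#' @return Integer vector of fold indices in 1..k, one per sample.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the ", n, " samples")
  withSeed(seed, {
    fold <- integer(n)
    if (min(table(labels)) < k) {
      warning("a class has fewer than k = ", k,
              " members; falling back to unstratified folds")
      fold <- (sample(n) - 1L) %% k + 1L
    } else {
      nextFold <- 0L
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- (nextFold + seq_along(idx) - 1L) %% k + 1L
        nextFold <- (nextFold + length(idx)) %% k
      }
    }
    fold
  })
}

#' Area under the ROC curve (rank estimator, ties one half)
#'
#' The probability that a randomly chosen positive sample is scored above a
#' randomly chosen negative one, with ties counted one half — computed via
#' midranks, which is exactly the exhaustive pairwise comparison.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels two-class factor.
#' @param positive positive-class label (defaults to the second level).
#' @return AUC in `[0, 1]`.
#' @examples
#' aucScore(c(0.1, 0.4, 0.35, 0.8), factor(c("n", "n", "p", "p")))
#' @export
aucScore <- function(scores, labels, positive = NULL) {
  y <- binaryResponse(labels, positive)
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Precision at a probability threshold
#'
#' Samples with score at or above `threshold` are called positive;
#' precision is TP / (TP + FP). When no sample is called positive the
#' precision is undefined and reported as `NA` (never silently zero).
#'
#' @inheritParams aucScore
#' @param threshold classification threshold on the score (default 0.5).
#' @return list with `precision` (`NA` if undefined) and `counts`
#'   (TP, FP, TN, FN).
#' @export
precisionAtThreshold <- function(scores, labels, threshold = 0.5,
                                 positive = NULL) {
  y <- binaryResponse(labels, positive)
  if (length(unique(y)) < 2L)
    stop("precision undefined: both classes must be present")
  call <- scores >= threshold
  counts <- c(TP = sum(call & y == 1L), FP = sum(call & y == 0L),
              TN = sum(!call & y == 0L), FN = sum(!call & y == 1L))
  prec <- if (counts[["TP"]] + counts[["FP"]] == 0L) NA_real_ else
    counts[["TP"]] / (counts[["TP"]] + counts[["FP"]])
  list(precision = prec, counts = counts)
}

#' Cross-validate L1 logistic selection on one dataset
#'
#' Stratified k-fold cross-validation: per fold, the penalty is chosen
#' within the training folds only (by the configured strategy), the model
#' is fit on the training folds and the held-out fold is scored. Held-out
#' scores are pooled — every sample scored exactly once — and AUC and
#' precision are computed on the pooled scores; per-fold metrics and wall
#' time are also reported. Timing is informational only (hardware
#' dependent).
#'
#' @param ds a non-empty [FilteredDataset-class] with both classes.
#' @param config a [solverConfig()].
#' @param k number of folds (default 5).
#' @param seed fold seed.
#' @param strategy penalty strategy, as in [selectFeatures()].
#' @param threshold precision threshold.
#' @return list of class `cvResult`: `foldAssignments`, `pooledScores`
#'   (named by sample), `auc`, `precision`, `counts`, `perFold`
#'   (data.frame with fold, auc, precision, lambda), `elapsedSeconds`.
#' @export
crossValidate <- function(ds, config = solverConfig(), k = 5L, seed = 1L,
                          strategy = c("inner-cv", "fixed"),
                          threshold = 0.5) {
  strategy <- match.arg(strategy)
  stopifnot(is(ds, "FilteredDataset"))
  if (nrow(ds) == 0L)
    stop("refusing to cross-validate empty dataset ", datasetType(ds))
  t0 <- proc.time()[["elapsed"]]
  X <- t(SummarizedExperiment::assay(ds))
  labels <- sampleLabels(ds)
  y <- binaryResponse(labels)
  fold <- stratifiedKFold(labels, k = k, seed = seed)
  scores <- rep(NA_real_, length(y))
  perFold <- data.frame(fold = seq_len(k), auc = NA_real_,
                        precision = NA_real_, lambda = NA_real_)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L)
      stop("fold ", f, " has a single class; cannot evaluate")
    cfgF <- config
    cfgF$seed <- deriveSeed(seed, f)
    choice <- chooseLambda(X[tr, , drop = FALSE], y[tr], cfgF, strategy)
    fit <- suppressWarnings(
      fitL1Logistic(X[tr, , drop = FALSE], y[tr], choice$lambda, cfgF))
    sc <- predict(fit, X[!tr, , drop = FALSE])
    scores[!tr] <- sc
    perFold$lambda[f] <- choice$lambda
    perFold$auc[f] <- aucScore(sc, labels[!tr])
    perFold$precision[f] <-
      precisionAtThreshold(sc, labels[!tr], threshold)$precision
  }
  pr <- precisionAtThreshold(scores, labels, threshold)
  structure(list(foldAssignments = setNames(fold, names(labels)),
                 pooledScores = setNames(scores, names(labels)),
                 auc = aucScore(scores, labels),
                 precision = pr$precision, counts = pr$counts,
                 perFold = perFold,
                 elapsedSeconds = proc.time()[["elapsed"]] - t0),
            class = "cvResult")
}

#' Percent feature reduction of a filter
#'
#' `100 * (raw - kept) / raw`: the share of raw features a pre-filter
#' removed.
#'
#' @param rawCount features before filtering (> 0).
#' @param keptCount features surviving the filter (0 <= kept <= raw).
#' @return Percentage in `[0, 100]`. Vectorized.
#' @examples
#' percentReduction(18756, 3604)  # 80.78...
#' @export
percentReduction <- function(rawCount, keptCount) {
  if (any(rawCount <= 0)) stop("rawCount must be positive")
  if (any(keptCount < 0) || any(keptCount > rawCount))
    stop("need 0 <= keptCount <= rawCount")
  100 * (rawCount - keptCount) / rawCount
}

#' Overlap analysis of selected feature sets
#'
#' Pairwise intersection counts between selections, the per-feature
#' occurrence histogram, and the recurrent features appearing in at least
#' `minOccurrence` selections (sorted by descending occurrence, then
#' identifier).
#'
#' @param selections list of [SelectionResult-class] objects or character
#'   vectors; names label the report rows/columns.
#' @param minOccurrence minimum number of selections a recurrent feature
#'   must appear in (default 2).
#' @return list with `pairwise` (symmetric integer matrix), `occurrence`
#'   (named integer vector) and `recurrent` (character vector).
#' @export
overlapAnalysis <- function(selections, minOccurrence = 2L) {
  if (length(selections) < 2L) stop("need at least two selections")
  sets <- lapply(selections, function(s)
    if (is(s, "SelectionResult")) selectedFeatures(s) else as.character(s))
  if (is.null(names(sets)))
    names(sets) <- paste0("selection", seq_along(sets))
  m <- length(sets)
  pairwise <- matrix(0L, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m)) for (j in seq_len(m))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  allFeat <- unlist(sets, use.names = FALSE)
  occ <- sort(table(allFeat), decreasing = TRUE)
  occurrence <- setNames(as.integer(occ), names(occ))
  rec <- names(occurrence)[occurrence >= minOccurrence]
  rec <- rec[order(-occurrence[rec], rec)]
  list(pairwise = pairwise, occurrence = occurrence, recurrent = rec)
}

#' Coverage of seed-enriched terms by a selected gene set
#'
#' Enriches the seed genes and the selected genes separately against the
#' same collection and returns the fraction of the seed list's enriched
#' terms that are also enriched in the selection:
#' `|E_seed intersect E_selected| / |E_seed|`. `NA` when the seed list
#' enriches no term.
#'
#' @param selectedGenes,seedGenes character vectors of feature
#'   identifiers.
#' @param coll an [AnnotationCollection] restricted to the measured
#'   universe.
#' @param alpha enrichment threshold (default 0.05, inclusive).
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @export
termCoverage <- function(selectedGenes, seedGenes, coll, alpha = 0.05) {
  eSeed <- suppressWarnings(enrichTerms(seedGenes, coll, alpha))$term
  if (!length(eSeed)) {
    warning("seed list enriches no term; coverage undefined")
    return(NA_real_)
  }
  eSel <- suppressWarnings(enrichTerms(selectedGenes, coll, alpha))$term
  length(intersect(eSeed, eSel)) / length(eSeed)
}
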