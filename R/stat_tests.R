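# Statistical primitives behind the pre-filters: the two-sample t-test
# (differential expression) and the hypergeometric over-representation test
# (gene-set enrichment). Threshold semantics throughout are inclusive:
# a feature/term passes at p <= alpha.

#' Two-sample t-test for one feature
#'
#' Welch's unequal-variance two-sided t-test by default (the robust choice
#' when per-class variances are not known to be equal); Student's pooled
#' test via `varEqual = TRUE`. Degenerate inputs where both classes have
#' zero variance are handled by convention: equal means give statistic 0
#' and p = 1, unequal means give an infinite statistic and p = 0.
#'
#' @param values numeric vector, one expression value per sample.
#' @param labels two-class factor (or named factor covering the values).
#' @param positive label of the positive class (defaults to the second
#'   factor level); only class membership matters for the test.
#' @param varEqual use Student's pooled-variance test instead of Welch.
#' @return list with `statistic` and `p.value` (two-sided).
#' @examples
#' twoSampleT(c(1, 2, 3, 4, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 4)))
#' @export
twoSampleT <- function(values, labels, positive = NULL, varEqual = FALSE) {
  y <- binaryResponse(labels, positive)
  g1 <- values[y == 1L]
  g0 <- values[y == 0L]
  if (length(g1) < 2L || length(g0) < 2L)
    stop("each class needs at least 2 samples (got ", length(g1), " and ",
         length(g0), ")")
  if (sd(g1) == 0 && sd(g0) == 0) {
    if (mean(g1) == mean(g0)) return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(g1) - mean(g0)) * Inf, p.value = 0))
  }
  tt <- stats::t.test(g1, g0, var.equal = varEqual)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Row-wise two-sample t-tests on an expression matrix
#'
#' Vectorized per-feature version of [twoSampleT()] used by the Type-2
#' filter; identical conventions (Welch default, inclusive thresholds
#' downstream, degenerate rows handled as in the scalar test).
#'
#' @param mat numeric matrix, features x samples.
#' @param labels two-class factor over the columns.
#' @inheritParams twoSampleT
#' @return data.frame with `feature`, `statistic`, `p.value`, one row per
#'   matrix row, in input order.
#' @export
rowTTest <- function(mat, labels, positive = NULL, varEqual = FALSE) {
  y <- binaryResponse(labels, positive)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("each class needs at least 2 samples (got ", n1, " and ", n0, ")")
  m1 <- rowMeans(mat[, y == 1L, drop = FALSE])
  m0 <- rowMeans(mat[, y == 0L, drop = FALSE])
  v1 <- rowSums((mat[, y == 1L, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((mat[, y == 0L, drop = FALSE] - m0)^2) / (n0 - 1)
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep.int(n1 + n0 - 2, nrow(mat))
  } else {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  stat <- (m1 - m0) / sqrt(se2)
  p <- 2 * pt(-abs(stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m0)
    stat[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m0)
    stat[ne] <- sign(m1[ne] - m0[ne]) * Inf; p[ne] <- 0
  }
  data.frame(feature = rownames(mat), statistic = unname(stat),
             p.value = unname(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail inclusive probability P(X >= n) for X hypergeometric with
#' population size `b`, `a` annotated successes, and `d` draws (the gene
#' list): the probability of seeing at least the observed overlap under the
#' null that the term is irrelevant to the list. Computed via the stable
#' log-space tail of the hypergeometric distribution. The strict tail
#' P(X > n) is available via `strict = TRUE`.
#'
#' @param a number of universe genes annotated to the term.
#' @param b universe (background) size.
#' @param d gene-list size.
#' @param n overlap between list and term.
#' @param strict use the exclusive tail P(X > n).
#' @return p-value in (0, 1].
#' @examples
#' hypergeomPValue(a = 5, b = 20, d = 5, n = 4)
#' @export
hypergeomPValue <- function(a, b, d, n, strict = FALSE) {
  stopifnot(length(a) == length(b), length(b) == length(d),
            length(d) == length(n))
  ok <- a >= 0 & d >= 0 & n >= 0 & a <= b & d <= b & n <= pmin(a, d)
  if (any(!ok))
    stop("invalid hypergeometric arguments; need 0 <= n <= min(a, d), ",
         "a <= b, d <= b")
  q <- if (strict) n else n - 1
  phyper(q, m = a, n = b - a, k = d, lower.tail = FALSE)
}

#' Gene-set enrichment of a gene list against a collection
#'
#' One hypergeometric test per term with `a = |term|` (after restriction to
#' the universe), `b = |universe|`, `d = |list|`, `n = |list` \eqn{\cap}
#' `term|`. List members outside the collection's universe are dropped with
#' a warning before testing. Terms with p <= `alpha` are returned, sorted
#' by p-value then term identifier, so the output order is total and
#' deterministic. No multiple-testing correction is applied by default
#' (each filter treats alpha as a plain per-term threshold);
#' Benjamini-Hochberg is available via `adjust = "BH"`, in which case the
#' threshold applies to the adjusted values.
#'
#' @param geneList character vector of feature identifiers.
#' @param coll an [AnnotationCollection], restricted to the measured
#'   universe (see [restrictToUniverse()]).
#' @param alpha inclusive significance threshold in (0, 1].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `term`, `a`, `b`, `d`, `n`, `p.value`
#'   (and `p.adjust` when adjusted), one row per enriched term.
#' @export
enrichTerms <- function(geneList, coll, alpha = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is(coll, "AnnotationCollection"), alpha > 0, alpha <= 1)
  univ <- universe(coll)
  if (!length(univ)) stop("collection has an empty universe")
  geneList <- unique(as.character(geneList))
  outside <- setdiff(geneList, univ)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the collection universe ",
            "dropped from the list")
    geneList <- intersect(geneList, univ)
  }
  empty <- data.frame(term = character(), a = integer(), b = integer(),
                      d = integer(), n = integer(), p.value = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(geneList)) {
    warning("empty gene list after restriction to the universe")
    return(empty)
  }
  sets <- lapply(geneSets(coll), intersect, y = univ)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) return(empty)
  b <- length(univ)
  d <- length(geneList)
  a <- lengths(sets)
  n <- vapply(sets, function(s) length(intersect(geneList, s)), 1L)
  p <- hypergeomPValue(a, rep.int(b, length(a)), rep.int(d, length(a)), n)
  res <- data.frame(term = names(sets), a = unname(a), b = b, d = d,
                    n = unname(n), p.value = unname(p),
                    stringsAsFactors = FALSE)
  if (adjust == "BH") {
    res$p.adjust <- p.adjust(res$p.value, method = "BH")
    keep <- res$p.adjust <= alpha
  } else {
    keep <- res$p.value <= alpha
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p.value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
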