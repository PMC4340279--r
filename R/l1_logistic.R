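# L1-penalized logistic regression, the feature-selection engine.
#
# Objective:  F(w, b) = L(w, b) + lambda * ||w||_1
# with L the mean Bernoulli negative log-likelihood under the logit link,
#   L(w, b) = (1/N) sum_i [ log(1 + exp(u_i)) - y_i * u_i ],
#   u_i = x_i' w + b,  y_i in {0, 1}.
# The intercept is never penalized. Solved by monotone FISTA (proximal
# gradient with Nesterov acceleration, backtracking line search and a
# descent restart), converged when the KKT residual drops below tol:
#   |dL/dw_j + lambda * sign(w_j)| <= tol   where w_j != 0
#   max(|dL/dw_j| - lambda, 0)     <= tol   where w_j  = 0
#   |dL/db|                        <= tol.
# Features are z-scored internally by default so a single lambda is
# comparable across features; reported weights are back-transformed to the
# original scale.

#' Solver configuration for L1 logistic regression
#'
#' @param lambda fixed penalty weight (>= 0); ignored under the `inner-cv`
#'   strategy of [selectFeatures()].
#' @param lambdaGridSize points on the log-spaced lambda grid used for
#'   cross-validated penalty choice (spanning `lambdaMax` down to
#'   `lambdaMax * lambdaMinRatio`).
#' @param lambdaMinRatio lower end of the grid as a fraction of the
#'   data-driven `lambdaMax`.
#' @param tolerance KKT residual at which a fit counts as converged.
#' @param maxIter iteration cap per fit.
#' @param cvTolerance,cvMaxIter looser convergence settings for the
#'   warm-started path fits used only to score candidate penalties during
#'   cross-validated lambda choice; held-out loss is insensitive to
#'   solving those fits to full precision, and the reported fit always
#'   uses `tolerance`/`maxIter`.
#' @param standardize z-score features inside the solver (training data
#'   only during cross-validation); weights are always reported on the
#'   original scale.
#' @param seed integer seed for the inner cross-validation folds.
#' @return A validated list of class `solverConfig`.
#' @export
solverConfig <- function(lambda = NULL, lambdaGridSize = 50L,
                         lambdaMinRatio = 1e-3, tolerance = 1e-6,
                         maxIter = 2000L, cvTolerance = 1e-4,
                         cvMaxIter = 100L, standardize = TRUE, seed = 1L) {
  stopifnot(tolerance > 0, maxIter >= 1, lambdaGridSize >= 2,
            lambdaMinRatio > 0, lambdaMinRatio < 1, cvTolerance > 0,
            cvMaxIter >= 1)
  if (!is.null(lambda)) stopifnot(lambda >= 0)
  structure(list(lambda = lambda, lambdaGridSize = as.integer(lambdaGridSize),
                 lambdaMinRatio = lambdaMinRatio, tolerance = tolerance,
                 maxIter = as.integer(maxIter), cvTolerance = cvTolerance,
                 cvMaxIter = as.integer(cvMaxIter),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "solverConfig")
}

#' Logistic loss and gradient
#'
#' Mean Bernoulli negative log-likelihood of a linear logit model and its
#' gradient with respect to the weights and intercept. The loss is convex;
#' at the origin with balanced classes it equals `log(2)`. Duplicating all
#' samples leaves it unchanged (it is an average).
#'
#' @param weights numeric weight vector (length = columns of `X`).
#' @param intercept scalar intercept.
#' @param X design matrix, samples x features.
#' @param y 0/1 response vector.
#' @return list with `loss`, `gradient` (per weight) and
#'   `interceptGradient`.
#' @export
logisticLossGrad <- function(weights, intercept, X, y) {
  u <- drop(X %*% weights) + intercept
  p <- plogis(u)
  n <- length(y)
  list(loss = mean(log1pexp(u) - y * u),
       gradient = drop(crossprod(X, p - y)) / n,
       interceptGradient = mean(p - y))
}

#' Smallest penalty with an all-zero optimal weight vector
#'
#' At `w = 0` with the intercept at the prevalence logit (its unpenalized
#' optimum), the largest absolute loss gradient over features is the
#' smallest lambda at which `w = 0` satisfies the KKT conditions — the top
#' of the regularization path.
#'
#' @param X design matrix, samples x features.
#' @param y 0/1 response with both classes present.
#' @param standardize evaluate on z-scored features (matching
#'   [fitL1Logistic()] with the same flag).
#' @return The penalty `lambdaMax` (0 when X carries no signal).
#' @export
lambdaMax <- function(X, y, standardize = TRUE) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("y must contain both classes")
  if (standardize) X <- standardizeDesign(X)$X
  pbar <- mean(y)
  max(abs(drop(crossprod(X, pbar - y))) / length(y), 0)
}

# z-score columns; zero-variance columns get scale 1 (their centered values
# are all zero, so their weight stays 0).
standardizeDesign <- function(X) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(X^2) - ctr^2)
  scl[scl < .Machine$double.eps] <- 1
  list(X = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

softThreshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Squared spectral norm of X by deterministic power iteration; a tight
# step size matters for the proximal gradient (the Frobenius bound is far
# too loose on wide designs). Backtracking guards any underestimate.
specNormSq <- function(X, iters = 30L) {
  pDim <- ncol(X)
  if (pDim == 0L) return(0)
  v <- rep.int(1 / sqrt(pDim), pDim)
  est <- 0
  for (i in seq_len(iters)) {
    u <- drop(crossprod(X, X %*% v))
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) return(0)
    v <- u / nrm
    est <- nrm
  }
  est
}

kktResidual <- function(g, gb, w, lambda) {
  atZero <- w == 0
  r <- numeric(length(w))
  r[atZero] <- pmax(abs(g[atZero]) - lambda, 0)
  r[!atZero] <- abs(g[!atZero] + lambda * sign(w[!atZero]))
  max(r, abs(gb))
}

# Core monotone-FISTA solve on an already-prepared design. Returns the
# solution on that design's scale.
l1Fista <- function(X, y, lambda, tol, maxIter, wInit = NULL, bInit = NULL,
                    stepInit = NULL) {
  n <- nrow(X); pDim <- ncol(X)
  w <- if (is.null(wInit)) numeric(pDim) else wInit
  b <- if (is.null(bInit)) qlogis(min(max(mean(y), 1e-12), 1 - 1e-12)) else
    bInit
  objective <- function(w, b) {
    u <- drop(X %*% w) + b
    mean(log1pexp(u) - y * u) + lambda * sum(abs(w))
  }
  grads <- function(w, b) {
    u <- drop(X %*% w) + b
    p <- plogis(u)
    list(loss = mean(log1pexp(u) - y * u),
         gw = drop(crossprod(X, p - y)) / n, gb = mean(p - y))
  }
  # Lipschitz constant of the smooth part is at most ||[X 1]||_2^2 / (4n)
  step <- if (is.null(stepInit)) 4 * n / (specNormSq(cbind(X, 1)) + 1e-12) else
    stepInit
  zW <- w; zB <- b          # extrapolation point
  tMom <- 1
  fX <- objective(w, b)
  converged <- FALSE; iter <- 0L; kkt <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    g <- grads(zW, zB)
    repeat {
      wNew <- softThreshold(zW - step * g$gw, step * lambda)
      bNew <- zB - step * g$gb
      uNew <- drop(X %*% wNew) + bNew
      lossNew <- mean(log1pexp(uNew) - y * uNew)
      dW <- wNew - zW; dB <- bNew - zB
      quad <- g$loss + sum(g$gw * dW) + g$gb * dB +
        (sum(dW^2) + dB^2) / (2 * step)
      if (lossNew <= quad + 1e-12) break
      step <- step / 2
    }
    fNew <- lossNew + lambda * sum(abs(wNew))
    if (fNew <= fX) {
      tNext <- (1 + sqrt(1 + 4 * tMom^2)) / 2
      zW <- wNew + ((tMom - 1) / tNext) * (wNew - w)
      zB <- bNew + ((tMom - 1) / tNext) * (bNew - b)
      w <- wNew; b <- bNew; fX <- fNew; tMom <- tNext
    } else {
      # descent restart: drop momentum, re-iterate from the current point
      zW <- w; zB <- b; tMom <- 1
    }
    gAt <- grads(w, b)
    kkt <- kktResidual(gAt$gw, gAt$gb, w, lambda)
    if (kkt <= tol) { converged <- TRUE; break }
  }
  list(weights = w, intercept = b, objective = fX, converged = converged,
       nIter = iter, kkt = kkt)
}

#' Fit an L1-penalized logistic regression
#'
#' Minimizes the mean logistic log-loss plus `lambda * ||w||_1` (intercept
#' unpenalized) by monotone accelerated proximal gradient with backtracking;
#' see the package vignette for the numerical conventions. At
#' `lambda >= lambdaMax(X, y)` the fit is exactly all-zero weights with the
#' intercept at the prevalence logit. Weights are reported on the original
#' feature scale regardless of internal standardization.
#'
#' @param X design matrix, samples x features (column names become
#'   coefficient names).
#' @param y 0/1 response (or two-level factor; second level = 1).
#' @param lambda penalty weight (>= 0).
#' @param config a [solverConfig()]; its `tolerance`, `maxIter` and
#'   `standardize` fields are used.
#' @param wInit,bInit optional warm start (on the internal scale used by
#'   the solver).
#' @return list of class `l1Fit`: `weights` (named, original scale),
#'   `intercept`, `lambda`, `objective` (internal-scale penalized
#'   objective), `converged`, `nIter`, `kkt`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
#' y <- rbinom(40, 1, plogis(X[, 1]))
#' fit <- fitL1Logistic(X, y, lambda = 0.05)
#' fit$weights
#' @export
fitL1Logistic <- function(X, y, lambda, config = solverConfig(),
                          wInit = NULL, bInit = NULL) {
  if (is.factor(y)) y <- binaryResponse(y)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), lambda >= 0, is.matrix(X),
            nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  std <- if (config$standardize) standardizeDesign(X) else
    list(X = X, center = numeric(ncol(X)), scale = rep.int(1, ncol(X)))
  sol <- l1Fista(std$X, y, lambda, config$tolerance, config$maxIter,
                 wInit = wInit, bInit = bInit)
  if (!sol$converged)
    warning("L1 logistic fit did not converge in ", config$maxIter,
            " iterations (KKT residual ", signif(sol$kkt, 3), ")")
  wOrig <- sol$weights / std$scale
  bOrig <- sol$intercept - sum(sol$weights * std$center / std$scale)
  # numerical-zero rule for penalized fits: rounding can leave O(eps)
  # residues exactly at the soft-threshold boundary (e.g. lambda = lambdaMax)
  if (lambda > 0) wOrig[abs(wOrig) < 1e-9] <- 0
  structure(list(weights = setNames(wOrig, colnames(X)), intercept = bOrig,
                 lambda = lambda, objective = sol$objective,
                 converged = sol$converged, nIter = sol$nIter,
                 kkt = sol$kkt,
                 internal = list(weights = sol$weights,
                                 intercept = sol$intercept)),
            class = "l1Fit")
}

# Warm-started fits over a decreasing lambda grid on a prepared design.
# Returns internal-scale weights (pDim x nLambda) and intercepts.
l1Path <- function(Xstd, y, lambdas, tol, maxIter) {
  pDim <- ncol(Xstd)
  W <- matrix(0, pDim, length(lambdas))
  B <- numeric(length(lambdas))
  w <- NULL; b <- NULL
  step <- 4 * nrow(Xstd) / (specNormSq(cbind(Xstd, 1)) + 1e-12)
  for (i in seq_along(lambdas)) {
    sol <- l1Fista(Xstd, y, lambdas[i], tol, maxIter, wInit = w, bInit = b,
                   stepInit = step)
    w <- sol$weights; b <- sol$intercept
    W[, i] <- w; B[i] <- b
  }
  list(W = W, B = B)
}

lambdaGrid <- function(lmax, size, minRatio) {
  if (lmax <= 0) return(rep.int(0, size))
  exp(seq(log(lmax), log(lmax * minRatio), length.out = size))
}

#' Predicted positive-class probabilities from an L1 fit
#'
#' @param object an `l1Fit` from [fitL1Logistic()].
#' @param newdata matrix of samples x features on the original scale.
#' @param ... ignored.
#' @return Vector of probabilities in (0, 1), monotone in the linear score.
#' @export
predict.l1Fit <- function(object, newdata, ...) {
  plogis(drop(newdata %*% object$weights) + object$intercept)
}

#' Select features on a pre-filtered dataset by L1 logistic regression
#'
#' Under the default `inner-cv` strategy the penalty is chosen on a
#' log-spaced grid from `lambdaMax` downward by stratified 5-fold mean
#' held-out log-loss (ties resolved toward the larger, sparser penalty),
#' then a single full-data fit at the chosen penalty yields the selection.
#' Under `fixed`, `config$lambda` is used directly. Features whose
#' back-transformed weight is below 1e-9 in magnitude count as zero.
#'
#' @param ds a non-empty [FilteredDataset-class] with both classes.
#' @param config a [solverConfig()].
#' @param strategy `"inner-cv"` (default) or `"fixed"`.
#' @return A [SelectionResult-class].
#' @export
selectFeatures <- function(ds, config = solverConfig(),
                           strategy = c("inner-cv", "fixed")) {
  strategy <- match.arg(strategy)
  stopifnot(is(ds, "FilteredDataset"))
  v <- if (is.na(datasetVariant(ds))) "" else paste0("-", datasetVariant(ds))
  if (nrow(ds) == 0L)
    stop("refusing to select on empty dataset ", datasetType(ds), v)
  X <- t(SummarizedExperiment::assay(ds))
  y <- binaryResponse(sampleLabels(ds))
  choice <- chooseLambda(X, y, config, strategy)
  fit <- fitL1Logistic(X, y, choice$lambda, config)
  nz <- which(abs(fit$weights) >= 1e-9)
  new("SelectionResult", datasetType = datasetType(ds),
      variant = datasetVariant(ds),
      selected = colnames(X)[nz],
      coefficients = fit$weights[nz],
      lambda = choice$lambda,
      fit = list(objective = fit$objective, converged = fit$converged,
                 nIter = fit$nIter, kkt = fit$kkt,
                 intercept = fit$intercept, lambdaMax = choice$lambdaMax,
                 cvLogLoss = choice$cvLogLoss))
}

# Penalty choice shared by selectFeatures and crossValidate. Returns the
# lambda plus diagnostics. For inner-cv: stratified k-fold held-out mean
# log-loss over the grid, computed with warm-started paths per fold.
chooseLambda <- function(X, y, config, strategy, k = 5L) {
  lmax <- lambdaMax(X, y, standardize = config$standardize)
  if (strategy == "fixed") {
    if (is.null(config$lambda))
      stop("strategy 'fixed' requires config$lambda")
    return(list(lambda = config$lambda, lambdaMax = lmax, cvLogLoss = NULL))
  }
  grid <- lambdaGrid(lmax, config$lambdaGridSize, config$lambdaMinRatio)
  if (lmax <= 0)
    return(list(lambda = 0, lambdaMax = 0, cvLogLoss = NULL))
  labs <- factor(y, levels = c(0, 1))
  names(labs) <- paste0("i", seq_along(y))
  folds <- stratifiedKFold(labs, k = k, seed = config$seed)
  heldOut <- matrix(NA_real_, length(grid), k)
  for (f in seq_len(k)) {
    tr <- folds != f
    std <- if (config$standardize) standardizeDesign(X[tr, , drop = FALSE]) else
      list(X = X[tr, , drop = FALSE], center = numeric(ncol(X)),
           scale = rep.int(1, ncol(X)))
    path <- l1Path(std$X, y[tr], grid, config$cvTolerance, config$cvMaxIter)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, std$center), 2L,
                 std$scale, "/")
    U <- Xte %*% path$W + rep(path$B, each = sum(!tr))
    yte <- y[!tr]
    heldOut[, f] <- colMeans(log1pexp(U) - yte * U)
  }
  mu <- rowMeans(heldOut)
  best <- which(mu <= min(mu) + 1e-12)[1L]  # ties -> larger (sparser) lambda
  list(lambda = grid[best], lambdaMax = lmax,
       cvLogLoss = data.frame(lambda = grid, logLoss = mu))
}
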