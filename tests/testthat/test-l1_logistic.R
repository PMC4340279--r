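test_that("logistic loss and gradient match closed form and finite differences", {
  inst <- randomLogisticInstance(n = 40, p = 5, seed = 1)
  # origin with balanced response: loss = ln 2
  yBal <- rep(c(0, 1), each = 20)
  expect_equal(logisticLossGrad(numeric(5), 0, inst$X, yBal)$loss, log(2))

  # gradient vs central finite differences
  set.seed(2)
  w <- rnorm(5, sd = 0.3); b <- 0.2
  g <- logisticLossGrad(w, b, inst$X, inst$y)
  eps <- 1e-6
  fd <- vapply(seq_along(w), function(j) {
    wp <- w; wm <- w
    wp[j] <- wp[j] + eps; wm[j] <- wm[j] - eps
    (logisticLossGrad(wp, b, inst$X, inst$y)$loss -
       logisticLossGrad(wm, b, inst$X, inst$y)$loss) / (2 * eps)
  }, 1)
  expect_equal(unname(g$gradient), fd, tolerance = 1e-6)
  fdB <- (logisticLossGrad(w, b + eps, inst$X, inst$y)$loss -
            logisticLossGrad(w, b - eps, inst$X, inst$y)$loss) / (2 * eps)
  expect_equal(g$interceptGradient, fdB, tolerance = 1e-6)

  # averaging invariance: duplicating every sample leaves the loss unchanged
  g2 <- logisticLossGrad(w, b, rbind(inst$X, inst$X), rep(inst$y, 2))
  expect_equal(g2$loss, g$loss)
})

test_that("lambdaMax is the exact threshold of the all-zero solution", {
  inst <- randomLogisticInstance(n = 50, p = 8, seed = 3)
  # no signal: zero
  X0 <- matrix(0, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(lambdaMax(X0, inst$y), 0)
  # linearity in X without standardization
  lm1 <- lambdaMax(inst$X, inst$y, standardize = FALSE)
  expect_equal(lambdaMax(2 * inst$X, inst$y, standardize = FALSE), 2 * lm1)
  expect_error(lambdaMax(inst$X, rep(1, 50)), "both classes")

  # KKT verification on random instances: just above lambdaMax the fit is
  # exactly zero; a bit below it is not
  for (s in 1:5) {
    inst <- randomLogisticInstance(n = 40, p = 6, seed = s)
    lmax <- lambdaMax(inst$X, inst$y)
    fitHi <- fitL1Logistic(inst$X, inst$y, 1.01 * lmax)
    expect_identical(unname(fitHi$weights), rep(0, 6))
    expect_equal(fitHi$intercept, qlogis(mean(inst$y)), tolerance = 1e-8)
    fitLo <- fitL1Logistic(inst$X, inst$y, 0.7 * lmax)
    expect_gt(sum(fitLo$weights != 0), 0)
  }
})

test_that("unpenalized fit agrees with the Newton (glm) MLE", {
  for (s in c(4, 9)) {
    inst <- randomLogisticInstance(n = 80, p = 4, seed = s)
    ref <- glm(inst$y ~ inst$X, family = binomial())
    fit <- fitL1Logistic(inst$X, inst$y, lambda = 0,
                         config = solverConfig(tolerance = 1e-9,
                                               maxIter = 50000))
    expect_equal(unname(fit$weights), unname(coef(ref)[-1]),
                 tolerance = 1e-6)
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  }
})

test_that("converged fits satisfy the KKT conditions on the solver scale", {
  set.seed(7)
  for (s in 1:12) {
    inst <- randomLogisticInstance(n = 40, p = 10, seed = 100 + s)
    lmax <- lambdaMax(inst$X, inst$y)
    lambda <- lmax * runif(1, 0.05, 0.9)
    cfg <- solverConfig(tolerance = 1e-7)
    fit <- fitL1Logistic(inst$X, inst$y, lambda, cfg)
    expect_true(fit$converged)
    std <- prefilterBench:::standardizeDesign(inst$X)
    g <- logisticLossGrad(fit$internal$weights, fit$internal$intercept,
                          std$X, inst$y)
    w <- fit$internal$weights
    atZero <- w == 0
    expect_lte(max(0, abs(g$gradient[atZero]) - lambda), cfg$tolerance)
    if (any(!atZero))
      expect_lte(max(abs(g$gradient[!atZero] + lambda * sign(w[!atZero]))),
                 cfg$tolerance)
    expect_lte(abs(g$interceptGradient), cfg$tolerance)
  }
})

test_that("support grows from empty as lambda decreases along the path", {
  inst <- randomLogisticInstance(n = 60, p = 15, seed = 21)
  lmax <- lambdaMax(inst$X, inst$y)
  grid <- exp(seq(log(lmax * 1.05), log(lmax * 0.01), length.out = 8))
  supports <- vapply(grid, function(l)
    sum(fitL1Logistic(inst$X, inst$y, l)$weights != 0), 1L)
  expect_identical(supports[1], 0L)
  expect_lte(supports[1], supports[length(supports)])
})

test_that("independent coordinate-descent solver agrees at matched penalty", {
  skip_if_not_installed("glmnet")
  inst <- randomLogisticInstance(n = 100, p = 6, seed = 31)
  lmax <- lambdaMax(inst$X, inst$y)
  lambda <- lmax / 4
  fit <- fitL1Logistic(inst$X, inst$y, lambda,
                       config = solverConfig(tolerance = 1e-9,
                                             maxIter = 20000))
  gn <- glmnet::glmnet(inst$X, inst$y, family = "binomial",
                       lambda = lambda, standardize = TRUE,
                       thresh = 1e-14, intercept = TRUE)
  expect_equal(unname(fit$weights), unname(as.numeric(gn$beta)),
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(gn$a0), tolerance = 1e-4)
})

test_that("selection recovers planted features and is deterministic", {
  # 10 strongly shifted features among 200: the selection should find most
  recalls <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    n <- 60; p <- 200
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(c(0L, 1L), each = n / 2)
    planted <- paste0("f", 1:10)
    X[y == 1L, planted] <- X[y == 1L, planted] + 2
    lab <- factor(ifelse(y == 1, "case", "ctrl"), levels = c("ctrl", "case"))
    names(lab) <- paste0("S", seq_len(n))
    dimnames(X) <- list(names(lab), colnames(X))
    ds <- FilteredDataset(t(X), lab, "type1")
    sel <- selectFeatures(ds, fastSolver(seed = s))
    mean(planted %in% selectedFeatures(sel))
  }, 1)
  expect_gte(median(recalls), 0.8)

  # bit-for-bit reproducibility given (dataset, config)
  study <- smallStudy(seed = 3, nGenes = 80, nMirnas = 10)
  ds <- buildType2(study@mrna, study@labels)
  s1 <- selectFeatures(ds, fastSolver(seed = 5))
  s2 <- selectFeatures(ds, fastSolver(seed = 5))
  expect_identical(selectedFeatures(s1), selectedFeatures(s2))
  expect_identical(coef(s1), coef(s2))

  # fixed lambda at or above lambdaMax selects nothing
  sFixed <- selectFeatures(ds, solverConfig(lambda = 10), strategy = "fixed")
  expect_length(selectedFeatures(sFixed), 0L)
  # empty dataset is refused by name
  empty <- suppressWarnings(buildType2(study@mrna, study@labels, 1e-300))
  expect_error(selectFeatures(empty), "empty dataset type2")
})

test_that("fitted probabilities are proper and monotone in the score", {
  inst <- randomLogisticInstance(n = 50, p = 5, seed = 77)
  fit <- fitL1Logistic(inst$X, inst$y, lambdaMax(inst$X, inst$y) / 5)
  pr <- predict(fit, inst$X)
  expect_true(all(pr > 0 & pr < 1))
  u <- drop(inst$X %*% fit$weights) + fit$intercept
  expect_identical(order(u), order(pr))
})
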