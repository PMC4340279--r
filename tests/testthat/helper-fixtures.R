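# Fixtures built in code; no stored data.

# tiny deterministic expression matrix
tinyMatrix <- function(nFeat = 3L, nSamp = 2L) {
  matrix(seq_len(nFeat * nSamp) / 2, nFeat, nSamp,
         dimnames = list(paste0("g", seq_len(nFeat)),
                         paste0("S", seq_len(nSamp))))
}

# small synthetic study at the package's default test scale
smallStudy <- function(seed = 1L, ...) {
  simulateStudy(simulationConfig(rngSeed = seed, ...))
}

# fast solver settings for tests that exercise behavior, not defaults
fastSolver <- function(seed = 1L, ...) {
  solverConfig(lambdaGridSize = 12L, lambdaMinRatio = 0.01, seed = seed, ...)
}

# brute-force hypergeometric upper tail: sum the point masses
# C(a,k) C(b-a,d-k) / C(b,d) over k = n..min(a,d), accumulated from the
# smallest terms; independent of phyper.
bruteHyperTail <- function(a, b, d, n) {
  ks <- seq(max(n, 0), min(a, d))
  if (!length(ks)) return(0)
  terms <- exp(lchoose(a, ks) + lchoose(b - a, d - ks) - lchoose(b, d))
  sum(sort(terms))
}

# exhaustive pairwise AUC with ties counted one half
pairwiseAUC <- function(scores, y) {
  sp <- scores[y == 1L]; sn <- scores[y == 0L]
  tot <- 0
  for (s in sp) tot <- tot + sum(s > sn) + 0.5 * sum(s == sn)
  tot / (length(sp) * length(sn))
}

# random two-class design, guaranteed non-separable by construction of a
# weak signal and overlapping classes
randomLogisticInstance <- function(n = 60L, p = 4L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- rnorm(p, sd = 0.5)
  y <- rbinom(n, 1L, plogis(drop(X %*% beta)))
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}
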