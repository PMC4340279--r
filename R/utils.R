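# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic stage-seed derivation; keeps results within 32-bit range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + as.numeric(offset) * 1009) %% 2147483629)
}

# y in {0,1} from a two-level factor of labels; positive defaults to the
# second factor level.
binaryResponse <- function(labels, positive = NULL) {
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) != 2L)
    stop("labels must contain exactly two classes, got ", length(lev))
  if (is.null(positive)) positive <- lev[2L]
  if (!positive %in% lev)
    stop("positive class '", positive, "' not present in labels")
  as.integer(as.character(labels) == positive)
}

# stable log(1 + exp(u))
log1pexp <- function(u) {
  out <- u
  small <- u <= 33
  out[small] <- log1p(exp(u[small]))
  out
}
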