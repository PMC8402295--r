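# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Descending order by score, ties broken by ascending feature index.
descendingOrder <- function(scores) {
  as.integer(order(-scores, seq_along(scores)))
}

newRankedList <- function(method, scores, featureNames) {
  new("RankedList", method = method, scores = as.numeric(scores),
      order = descendingOrder(scores), featureNames = featureNames)
}

# Derive a vector of sub-seeds (< 2^31) from a master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}
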