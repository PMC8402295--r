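# Independent brute-force oracles used to cross-check the filter scores and
# the wrapper search. These deliberately take different computational routes
# than the package (entropy identities, explicit double loops, exhaustive
# enumeration).

# Mutual information in bits via H(M) + H(N) - H(M,N).
oracleMI <- function(bins, labels) {
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  tab <- table(bins, labels)
  ent(rowSums(tab)) + ent(colSums(tab)) - ent(as.vector(tab))
}

# Pearson chi-square by explicit cell-by-cell summation.
oracleChisq <- function(bins, labels) {
  tab <- table(bins, labels)
  z <- sum(tab)
  out <- 0
  for (m in seq_len(nrow(tab))) {
    for (n in seq_len(ncol(tab))) {
      e <- sum(tab[m, ]) * sum(tab[, n]) / z
      if (e > 0) out <- out + (tab[m, n] - e)^2 / e
    }
  }
  out
}

# Sum over classes of the within-class sample variance, written out by hand.
oracleXV <- function(v, labels) {
  out <- 0
  for (cl in unique(labels)) {
    g <- v[labels == cl]
    if (length(g) >= 2) out <- out + sum((g - mean(g))^2) / (length(g) - 1)
  }
  out
}

# Pearson correlation by direct plug-in of the covariance formula.
oracleCorr <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Exhaustive search over all non-empty masks of a small candidate set,
# using the same fitness contract as the wrapper.
oracleBestSubset <- function(x, candidates, config) {
  d <- length(candidates)
  stopifnot(d <= 12)
  best <- NULL
  for (code in seq_len(2^d - 1L)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(d) - 1L)) > 0)
    sol <- woaFitness(x, candidates, mask, config)
    if (is.null(best) || sol@fitness < best@fitness) best <- sol
  }
  best
}

# A tiny two-class dataset with one perfectly separating feature.
makeTinyDataset <- function(n = 20, nNoise = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  sep <- ifelse(y == "b", 1, 0)
  m <- cbind(sep, matrix(runif(n * nNoise), n, nNoise))
  colnames(m) <- c("sep", paste0("noise", seq_len(nNoise)))
  FSDataset(m, y)
}
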