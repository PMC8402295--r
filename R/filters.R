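#' Equal-frequency discretization
#'
#' Bins a numeric column into at most `nBins` bins of (as nearly as ties
#' allow) equal occupancy.  Identical values always share a bin, and bin
#' identifiers are contiguous integers starting at 0.  Used to turn
#' continuous expression values into the discrete events the mutual
#' information and chi-square filters require.
#'
#' @param column numeric vector.
#' @param nBins maximum number of bins, at least 2.
#' @return integer vector of bin ids in `0:(b-1)` with `b <= nBins`.
#' @examples
#' discretizeEqualFreq(c(5, 1, 3, 2, 4, 6), 3)
#' @export
discretizeEqualFreq <- function(column, nBins = 10L) {
  if (length(column) == 0L) stop("empty column")
  if (nBins < 2L) stop("'nBins' must be at least 2")
  if (anyNA(column)) stop("missing values in column")
  breaks <- unique(stats::quantile(column,
                                   probs = seq_len(nBins - 1L) / nBins,
                                   type = 1, names = FALSE))
  bins <- findInterval(column, breaks, left.open = TRUE)
  as.integer(match(bins, sort(unique(bins))) - 1L)
}

# Joint contingency table of a discretized feature vs the class factor.
contingency <- function(bins, labels) {
  table(bins, labels)
}

# Plug-in mutual information (bits) from a contingency table.
miFromTable <- function(tab) {
  z <- sum(tab)
  p <- tab / z
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# Pearson chi-square statistic from a contingency table; expected counts
# from the marginals. Cells with zero expected count contribute 0 (they can
# only arise from an empty row/column, where observed is 0 too).
chisqFromTable <- function(tab) {
  z <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / z
  nz <- e > 0
  sum((tab[nz] - e[nz])^2 / e[nz])
}

#' Rank features by mutual information with the class
#'
#' Each feature is discretized by equal-frequency binning and its mutual
#' information with the class label, I(feature; class) = H(class) -
#' H(class | feature), is estimated by the plug-in estimator on the
#' empirical joint distribution, in bits.  Higher is better; a value of 0
#' means the discretized feature and the class are empirically independent.
#'
#' @param x a preprocessed [FSDataset-class].
#' @param nBins bins for [discretizeEqualFreq()].
#' @return a [RankedList-class] with method `"MI"`.
#' @export
rankMutualInformation <- function(x, nBins = 10L) {
  f <- featureMatrix(x)
  y <- classLabels(x)
  s <- apply(f, 2L, function(v)
    miFromTable(contingency(discretizeEqualFreq(v, nBins), y)))
  newRankedList("MI", s, featureNames(x))
}

#' Rank features by the chi-square statistic against the class
#'
#' Each feature is discretized by equal-frequency binning; the Pearson
#' chi-square statistic of the bins-by-classes contingency table (expected
#' counts from the marginals) measures departure from independence.  Higher
#' is better: a larger statistic means stronger dependence between feature
#' and class.
#'
#' @inheritParams rankMutualInformation
#' @return a [RankedList-class] with method `"CS"`.
#' @export
rankChiSquare <- function(x, nBins = 10L) {
  f <- featureMatrix(x)
  y <- classLabels(x)
  s <- apply(f, 2L, function(v)
    chisqFromTable(contingency(discretizeEqualFreq(v, nBins), y)))
  newRankedList("CS", s, featureNames(x))
}

#' Rank features by multiclass ReliefF
#'
#' For each (sampled) instance, ReliefF finds its `kNeighbors` nearest
#' hits (same class) and, for every other class, its `kNeighbors` nearest
#' misses.  Each feature's weight is decreased by the averaged hit
#' differences and increased by the miss differences, the latter weighted
#' by the miss class's prior over one minus the instance's class prior.
#' Distances between instances are Manhattan over all features; per-feature
#' differences are normalized by the feature's range.  Neighbour ties are
#' broken by ascending sample index, so with full sampling the ranking is
#' deterministic.
#'
#' @param x an [FSDataset-class] with features normalized to `[0, 1]`.
#' @param kNeighbors hits/misses per class (default 10).
#' @param nSampled number of instances to sample, or `NULL` (default) to
#'   use every instance deterministically.
#' @param seed seed for instance sampling when `nSampled` is given.
#' @return a [RankedList-class] with method `"RFF"`.
#' @export
rankReliefF <- function(x, kNeighbors = 10L, nSampled = NULL, seed = 1L) {
  f <- featureMatrix(x)
  y <- classLabels(x)
  n <- nrow(f)
  tab <- table(y)
  if (any(tab < kNeighbors + 1L))
    stop("every class needs more than 'kNeighbors' samples for ReliefF")
  prior <- as.numeric(tab) / n
  names(prior) <- names(tab)

  rng <- apply(f, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- 1        # constant feature: all diffs are 0 anyway
  fn <- sweep(f, 2L, rng, "/")

  idx <- if (is.null(nSampled) || nSampled >= n) seq_len(n)
         else withSeed(seed, sort(sample.int(n, nSampled)))

  # full Manhattan distance matrix on range-normalized features
  D <- as.matrix(stats::dist(fn, method = "manhattan"))

  w <- numeric(ncol(f))
  m <- length(idx)
  for (i in idx) {
    di <- D[i, ]
    for (cl in levels(y)) {
      members <- which(y == cl)
      members <- members[members != i]
      nb <- members[order(di[members], members)][seq_len(kNeighbors)]
      contrib <- colSums(abs(fn[nb, , drop = FALSE] -
                             matrix(fn[i, ], kNeighbors, ncol(f),
                                    byrow = TRUE)))
      if (cl == as.character(y[i])) {
        w <- w - contrib / (m * kNeighbors)
      } else {
        w <- w + (prior[cl] / (1 - prior[as.character(y[i])])) *
          contrib / (m * kNeighbors)
      }
    }
  }
  newRankedList("RFF", w, featureNames(x))
}

#' Rank features by the Xvariance score
#'
#' The Xvariance of a feature is the sum over classes of the within-class
#' sample variance (n-1 denominator) of the feature's values; singleton
#' classes contribute 0.  Higher values rank better in this framework.
#'
#' @param x a preprocessed [FSDataset-class].
#' @return a [RankedList-class] with method `"XV"`.
#' @export
rankXVariance <- function(x) {
  f <- featureMatrix(x)
  y <- classLabels(x)
  s <- numeric(ncol(f))
  for (cl in levels(y)) {
    sub <- f[y == cl, , drop = FALSE]
    if (nrow(sub) < 2L) next
    s <- s + apply(sub, 2L, stats::var)
  }
  newRankedList("XV", s, featureNames(x))
}

#' Accessors for RankedList
#'
#' `rankMethod` returns the filter identifier, `scores` the per-feature
#' scores, `featureOrder` the permutation of feature indices sorted by
#' descending desirability (ties broken by ascending index).
#'
#' @param x a [RankedList-class].
#' @return the corresponding slot.
#' @name RankedList-accessors
NULL

#' @rdname RankedList-accessors
#' @export
setMethod("rankMethod", "RankedList", function(x) x@method)

#' @rdname RankedList-accessors
#' @export
setMethod("scores", "RankedList",
          function(x) stats::setNames(x@scores, x@featureNames))

#' @rdname RankedList-accessors
#' @export
setMethod("featureOrder", "RankedList", function(x) x@order)

setMethod("show", "RankedList", function(object) {
  cat("RankedList (", object@method, "), ", length(object@scores),
      " features\n", sep = "")
  top <- utils::head(object@order, 5L)
  cat("top:", paste0(object@featureNames[top], " (",
                     signif(object@scores[top], 4), ")",
                     collapse = ", "), "\n")
  invisible(NULL)
})

#' Write a ranking to a two-column TSV
#'
#' @param x a [RankedList-class].
#' @param path output path; rows are (feature_name, score), best first.
#' @return `path`, invisibly.
#' @export
writeRanking <- function(x, path) {
  df <- data.frame(feature_name = x@featureNames[x@order],
                   score = x@scores[x@order])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
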