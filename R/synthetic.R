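#' Generate a classification dataset with planted structure
#'
#' Emulates the shape of gene-expression classification tables: tens to
#' hundreds of samples, hundreds to thousands of features, a small set of
#' class-informative features, correlated redundant copies of each, and
#' independent noise.  Informative features follow class-conditional
#' normals with unit variance and class means `0, effectSize,
#' 2 effectSize, ...`, so `effectSize` is the standardized mean shift
#' between adjacent classes.  Each redundant copy is its source plus
#' Gaussian noise whose variance is calibrated from the source's marginal
#' (mixture) variance so that the population correlation with the source is
#' exactly `redundancyRho`.  Noise features are iid standard normal,
#' independent of the class.  Optionally, cells are knocked out at random
#' to exercise imputation.  Fully determined by `seed`.
#'
#' @param nSamples number of samples (split as evenly as possible across
#'   classes); at least `2 * nClasses`.
#' @param nInformative number of informative features.
#' @param nRedundantPerInformative redundant copies planted per informative
#'   feature.
#' @param nNoise number of class-independent noise features.
#' @param nClasses number of classes (default 2).
#' @param effectSize standardized between-class mean shift on informative
#'   features (default 1.5).
#' @param redundancyRho population correlation between a redundant copy and
#'   its source, in (-1, 1) excluding 0 (default 0.9).
#' @param missingRate fraction of cells set missing, in [0, 1) (default 0).
#' @param seed integer seed.
#' @return list with elements `dataset` (an [FSDataset-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' g <- syntheticDataset(nSamples = 20, nInformative = 2,
#'                       nRedundantPerInformative = 1, nNoise = 5, seed = 1)
#' g$dataset
#' @export
syntheticDataset <- function(nSamples = 60L, nInformative = 5L,
                             nRedundantPerInformative = 2L, nNoise = 100L,
                             nClasses = 2L, effectSize = 1.5,
                             redundancyRho = 0.9, missingRate = 0,
                             seed = 1L) {
  if (nSamples < 2L * nClasses)
    stop("'nSamples' must be at least 2 * nClasses")
  if (nInformative < 0L || nRedundantPerInformative < 0L || nNoise < 0L)
    stop("feature counts must be non-negative")
  if (abs(redundancyRho) >= 1 || redundancyRho == 0)
    stop("'redundancyRho' must lie in (-1, 1) and be non-zero")
  if (missingRate < 0 || missingRate >= 1)
    stop("'missingRate' must lie in [0, 1)")

  labels <- factor(rep_len(paste0("c", seq_len(nClasses)), nSamples))
  labels <- labels[order(labels)]
  mu <- effectSize * (as.integer(labels) - 1L)

  # population (mixture) variance of an informative feature
  prop <- as.numeric(table(labels)) / nSamples
  mus <- effectSize * (seq_len(nClasses) - 1L)
  varMu <- sum(prop * mus^2) - sum(prop * mus)^2
  tau <- sqrt((1 + varMu) * (1 / redundancyRho^2 - 1))

  p <- nInformative * (1L + nRedundantPerInformative) + nNoise
  withSeed(seed, {
    m <- matrix(NA_real_, nSamples, p)
    nms <- character(p)
    informative <- integer(nInformative)
    groups <- vector("list", nInformative)
    col <- 0L
    for (i in seq_len(nInformative)) {
      col <- col + 1L
      src <- stats::rnorm(nSamples, mean = mu)
      m[, col] <- src
      nms[col] <- paste0("inf", i)
      informative[i] <- col
      copies <- integer(nRedundantPerInformative)
      for (q in seq_len(nRedundantPerInformative)) {
        col <- col + 1L
        m[, col] <- src + tau * stats::rnorm(nSamples)
        nms[col] <- paste0("inf", i, "_r", q)
        copies[q] <- col
      }
      groups[[i]] <- copies
    }
    if (nNoise > 0L) {
      noiseIdx <- (col + 1L):p
      m[, noiseIdx] <- stats::rnorm(nSamples * nNoise)
      nms[noiseIdx] <- paste0("noise", seq_len(nNoise))
    } else noiseIdx <- integer()
    if (missingRate > 0) {
      drop <- stats::runif(length(m)) < missingRate
      m[drop] <- NA_real_
    }
    colnames(m) <- nms
    names(groups) <- nms[informative]
    list(dataset = FSDataset(m, labels),
         truth = new("GroundTruth", informative = informative,
                     groups = groups, noise = as.integer(noiseIdx)))
  })
}

#' Fraction of planted informative groups recovered by a selection
#'
#' A group counts as recovered when the selection contains its informative
#' feature or any of the feature's redundant copies.
#'
#' @param selected integer vector of selected feature indices.
#' @param truth a [GroundTruth-class].
#' @return fraction in `[0, 1]` (0 when there are no informative groups).
#' @export
recoveryScore <- function(selected, truth) {
  stopifnot(is(truth, "GroundTruth"))
  if (length(truth@informative) == 0L) return(0)
  hit <- vapply(seq_along(truth@informative), function(i) {
    any(c(truth@informative[i], truth@groups[[i]]) %in% selected)
  }, logical(1))
  mean(hit)
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@informative), "informative groups (",
      length(unlist(object@groups)), "redundant copies ),",
      length(object@noise), "noise features\n")
  invisible(NULL)
})
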