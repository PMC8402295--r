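#' Pairwise and feature-to-class Pearson correlations
#'
#' Computes the Pearson correlation coefficient between every pair of the
#' given features, and between each feature and the class encoded as
#' consecutive integers in sorted label order (0/1 for binary problems).
#' Correlations involving a constant feature are defined as 0 (the
#' denominator vanishes), so constant features are never flagged as
#' redundant.
#'
#' @param x an [FSDataset-class] with at least 3 samples.
#' @param features integer vector (length >= 2) of feature indices; the
#'   order is preserved and should be the Stage-1 rank order when the
#'   result feeds [pruneCorrelated()].
#' @return a [CorrelationResult-class].
#' @export
featureCorrelations <- function(x, features) {
  if (length(features) < 2L) stop("need at least 2 features")
  f <- featureMatrix(x)[, features, drop = FALSE]
  if (nrow(f) < 3L) stop("need at least 3 samples")
  r <- suppressWarnings(stats::cor(f))
  const <- apply(f, 2L, function(v) stats::var(v) == 0)
  r[const, ] <- 0
  r[, const] <- 0
  diag(r)[!const] <- 1
  yNum <- as.numeric(classLabels(x)) - 1
  classR <- suppressWarnings(as.numeric(stats::cor(f, yNum)))
  classR[is.na(classR)] <- 0
  dimnames(r) <- NULL
  new("CorrelationResult", r = r, classR = classR,
      features = as.integer(features),
      featureNames = featureNames(x)[features])
}

#' Redundancy pruning by Pearson correlation
#'
#' Walks the feature pairs in rank order (outer index ascending, inner
#' ascending).  Whenever both members of a pair are still kept and their
#' absolute correlation exceeds the threshold, the member with the smaller
#' absolute class correlation is discarded (ties discard the later-ranked
#' one).  Pairs are only ever tested between currently-kept features, and a
#' feature with no above-threshold partner is never discarded.  After
#' pruning, no kept pair has |r| above the threshold.
#'
#' @param cm a [CorrelationResult-class] whose feature order is the Stage-1
#'   rank order.
#' @param threshold correlation threshold in (0, 1); the pair is redundant
#'   when |r| is strictly greater (default 0.7).
#' @return a [PruneResult-class].
#' @export
pruneCorrelated <- function(cm, threshold = 0.7) {
  stopifnot(is(cm, "CorrelationResult"))
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0,1)")
  p <- length(cm@features)
  kept <- rep(TRUE, p)
  disc <- list()
  for (i in seq_len(p - 1L)) {
    if (!kept[i]) next
    for (j in (i + 1L):p) {
      if (!kept[i]) break
      if (!kept[j]) next
      if (abs(cm@r[i, j]) > threshold) {
        drop <- if (abs(cm@classR[j]) > abs(cm@classR[i])) i else j
        keep <- if (drop == i) j else i
        kept[drop] <- FALSE
        disc[[length(disc) + 1L]] <- data.frame(
          discarded = cm@features[drop],
          retained = cm@features[keep],
          r = cm@r[i, j])
      }
    }
  }
  audit <- if (length(disc)) do.call(rbind, disc)
           else data.frame(discarded = integer(), retained = integer(),
                           r = numeric())
  new("PruneResult", kept = cm@features[kept], discarded = audit,
      threshold = threshold)
}

#' Accessors for PruneResult
#'
#' `keptFeatures` returns the surviving feature indices in rank order;
#' `discardAudit` the data.frame of (discarded, retained, r) triples.
#'
#' @param x a [PruneResult-class].
#' @return the corresponding slot.
#' @name PruneResult-accessors
NULL

#' @rdname PruneResult-accessors
#' @export
setMethod("keptFeatures", "PruneResult", function(x) x@kept)

#' @rdname PruneResult-accessors
#' @export
setMethod("discardAudit", "PruneResult", function(x) x@discarded)

setMethod("show", "PruneResult", function(object) {
  cat("PruneResult:", length(object@kept), "features kept,",
      nrow(object@discarded), "discarded at |r| >", object@threshold, "\n")
  invisible(NULL)
})

#' Phase-2 truncation of the pruned feature list
#'
#' Applies the same plateau rule as Phase 1 ([plateauSelect()]) to the
#' pruned, rank-ordered features, yielding the top-j subset handed to the
#' wrapper stage.
#'
#' @inheritParams plateauSelect
#' @param keptFeatures integer vector of surviving features in rank order
#'   (from [pruneCorrelated()]).
#' @return a [StageResult-class].
#' @export
selectTopJ <- function(x, keptFeatures, coarseStep = 5L, cvFolds = 10L,
                       seed = 1L, nrounds = 30L, nRepeats = 10L) {
  plateauSelect(x, keptFeatures, coarseStep = coarseStep,
                cvFolds = cvFolds, seed = seed, nrounds = nrounds,
                nRepeats = nRepeats)
}
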