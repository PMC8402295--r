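#' Union of the top-m features of the four filter rankings
#'
#' Pools the first `m` entries of each ranking's order into one candidate
#' set.  Exactly the four Stage-1 rankers (MI, CS, RFF, XV) must be
#' supplied; the union has between `m` and `4 m` features.
#'
#' @param rankedLists list of four [RankedList-class] objects covering the
#'   methods MI, CS, RFF and XV (in any order).
#' @param m prefix length per ranking; must not exceed the feature count.
#' @return sorted integer vector of the union's feature indices.
#' @export
unionTopM <- function(rankedLists, m) {
  if (length(rankedLists) != 4L ||
      !all(vapply(rankedLists, is, logical(1), "RankedList")))
    stop("supply a list of exactly four RankedList objects")
  methods <- vapply(rankedLists, rankMethod, character(1))
  if (!setequal(methods, c("MI", "CS", "RFF", "XV")))
    stop("the four rankings must cover MI, CS, RFF and XV")
  p <- length(scores(rankedLists[[1L]]))
  if (m > p) stop("'m' exceeds the feature count")
  if (m < 1L) stop("'m' must be positive")
  sort(unique(unlist(lapply(rankedLists,
                            function(r) featureOrder(r)[seq_len(m)]))))
}

#' Score each candidate feature individually with three classifiers
#'
#' Every candidate feature is evaluated alone with KNN, SVM and naive Bayes
#' under one shared seeded stratified fold assignment (identical folds
#' across classifiers and features, so the resulting means are comparable),
#' and the arithmetic mean of the three pooled cross-validated accuracies
#' is recorded.
#'
#' @param x a preprocessed [FSDataset-class].
#' @param candidates integer vector of candidate feature indices.
#' @param cvFolds folds for the stratified cross-validation (default 10).
#' @param seed fold-assignment seed.
#' @param knnK neighbours for the KNN classifier (default 5).
#' @return data.frame with columns `feature`, `featureName`, `knn`, `svm`,
#'   `nb`, `mean`, one row per candidate in the order given.
#' @export
scoreFeaturesIndividually <- function(x, candidates, cvFolds = 10L,
                                      seed = 1L, knnK = 5L) {
  if (length(candidates) == 0L) stop("no candidate features")
  y <- classLabels(x)
  fid <- stratifiedFolds(y, cvFolds, seed)
  accOne <- function(fi, spec) {
    mean(cvPredict(x, fi, spec, fid, seed, list(knnK = knnK))$pred == y)
  }
  knn <- vapply(candidates, accOne, numeric(1), spec = "knn")
  svm <- vapply(candidates, accOne, numeric(1), spec = "svm")
  nb <- vapply(candidates, accOne, numeric(1), spec = "nb")
  data.frame(feature = as.integer(candidates),
             featureName = featureNames(x)[candidates],
             knn = knn, svm = svm, nb = nb,
             mean = (knn + svm + nb) / 3)
}

#' Sort features by descending mean single-feature accuracy
#'
#' @param records data.frame from [scoreFeaturesIndividually()].
#' @return integer vector of feature indices, best first; ties broken by
#'   ascending feature index.
#' @export
sortByMeanAccuracy <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  records$feature[order(-records$mean, records$feature)]
}

#' Plateau-based truncation of a ranked feature list
#'
#' Evaluates an XGBoost classifier with seeded stratified cross-validation
#' on nested prefixes of the ordered features: first on coarse sizes
#' `coarseStep, 2 coarseStep, ...` up to the full length, then on every
#' size within `coarseStep` of the best coarse size.  The selected size is
#' the smallest evaluated prefix attaining the global maximum accuracy --
#' beyond it, accuracy only stays the same or decreases among the evaluated
#' sizes.
#'
#' On small-sample tables a single cross-validated trace is granular (steps
#' of 1/n) and its argmax is noise-sensitive, so each prefix accuracy is
#' averaged over `nRepeats` independent seeded fold assignments; the same
#' assignments are shared by every prefix size, keeping the trace
#' comparable across sizes.
#'
#' @param x a preprocessed [FSDataset-class].
#' @param orderedFeatures integer vector of feature indices, best first.
#' @param coarseStep coarse scan stride (default 5).
#' @param cvFolds stratified folds (default 10).
#' @param seed fold-assignment and XGBoost seed.
#' @param nrounds boosting rounds per fit (default 30).
#' @param nRepeats fold assignments to average each prefix accuracy over
#'   (default 10).
#' @return a [StageResult-class].
#' @export
plateauSelect <- function(x, orderedFeatures, coarseStep = 5L,
                          cvFolds = 10L, seed = 1L, nrounds = 30L,
                          nRepeats = 10L) {
  L <- length(orderedFeatures)
  if (L == 0L) stop("no features to select from")
  y <- classLabels(x)
  repSeeds <- deriveSeeds(seed, nRepeats)
  fids <- lapply(repSeeds, function(s) stratifiedFolds(y, cvFolds, s))
  evalPrefix <- function(size) {
    fi <- orderedFeatures[seq_len(size)]
    mean(vapply(seq_len(nRepeats), function(r) {
      opts <- list(nrounds = nrounds, seed = repSeeds[r])
      mean(cvPredict(x, fi, "xgb", fids[[r]], repSeeds[r], opts)$pred == y)
    }, numeric(1)))
  }
  coarse <- unique(c(seq(min(coarseStep, L), L, by = coarseStep), L))
  acc <- vapply(coarse, evalPrefix, numeric(1))
  best <- coarse[which.max(acc)]   # earliest max -> smallest coarse argmax
  refine <- setdiff(max(1L, best - coarseStep):min(L, best + coarseStep),
                    coarse)
  if (length(refine)) {
    acc <- c(acc, vapply(refine, evalPrefix, numeric(1)))
    coarse <- c(coarse, refine)
  }
  ord <- order(coarse)
  trace <- data.frame(size = coarse[ord], accuracy = acc[ord])
  sel <- min(trace$size[trace$accuracy >= max(trace$accuracy) - 1e-12])
  new("StageResult", orderedFeatures = as.integer(orderedFeatures),
      selectedSize = as.integer(sel), trace = trace)
}

#' Accessors for StageResult
#'
#' `orderedFeatures` returns the full ordered candidate list,
#' `selectedSize` the chosen prefix length, `selectedFeatures` the chosen
#' prefix itself, and `accuracyTrace` the data.frame of evaluated prefix
#' sizes and their cross-validated accuracies.
#'
#' @param x a [StageResult-class].
#' @return the corresponding slot or derived vector.
#' @name StageResult-accessors
NULL

#' @rdname StageResult-accessors
#' @export
setMethod("orderedFeatures", "StageResult", function(x) x@orderedFeatures)

#' @rdname StageResult-accessors
#' @export
setMethod("selectedSize", "StageResult", function(x) x@selectedSize)

#' @rdname StageResult-accessors
#' @export
setMethod("selectedFeatures", "StageResult",
          function(x) x@orderedFeatures[seq_len(x@selectedSize)])

#' @rdname StageResult-accessors
#' @export
setMethod("accuracyTrace", "StageResult", function(x) x@trace)

setMethod("show", "StageResult", function(object) {
  tr <- object@trace
  cat("StageResult:", object@selectedSize, "of",
      length(object@orderedFeatures), "features selected\n")
  cat(sprintf("best CV accuracy %.4f over %d evaluated prefix sizes\n",
              max(tr$accuracy), nrow(tr)))
  invisible(NULL)
})
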