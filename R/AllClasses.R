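#' @import methods
NULL

#' FSDataset: a classification table for feature selection
#'
#' Container for a numeric samples-by-features matrix together with a
#' categorical class label per sample and a mask recording which cells were
#' missing in the source file before imputation.
#'
#' Column names of the feature matrix are the feature names and must be
#' unique.  Feature-selection stages address features by column index into
#' this matrix, so the column order is significant and is preserved by all
#' operations.
#'
#' @slot features numeric matrix, samples in rows, features in columns;
#'   `colnames` hold the (unique) feature names.
#' @slot labels factor of class labels, one per row of `features`.
#' @slot missingMask logical matrix of the same shape as `features`; `TRUE`
#'   marks cells that were missing in the original input.
#'
#' @seealso [FSDataset()], [readTabular()], [imputeClasswiseMean()],
#'   [standardizeNormalize()]
#' @export
setClass("FSDataset",
  representation(
    features    = "matrix",
    labels      = "factor",
    missingMask = "matrix"
  )
)

setValidity("FSDataset", function(object) {
  msg <- character()
  f <- object@features
  if (!is.numeric(f))
    msg <- c(msg, "'features' must be a numeric matrix")
  if (length(object@labels) != nrow(f))
    msg <- c(msg, "number of labels must equal the number of sample rows")
  fn <- colnames(f)
  if (is.null(fn) || anyNA(fn) || any(fn == ""))
    msg <- c(msg, "every feature column must be named")
  else if (anyDuplicated(fn))
    msg <- c(msg, "feature names must be unique")
  if (!identical(dim(object@missingMask), dim(f)))
    msg <- c(msg, "'missingMask' must have the same dimensions as 'features'")
  if (!is.logical(object@missingMask))
    msg <- c(msg, "'missingMask' must be logical")
  tab <- table(droplevels(object@labels))
  if (length(tab) < 2L)
    msg <- c(msg, "at least 2 distinct classes are required")
  else if (any(tab < 2L))
    msg <- c(msg, "every class needs at least 2 samples")
  if (length(msg)) msg else TRUE
})

#' RankedList: one filter's ordering of all features
#'
#' @slot method single string, one of `"MI"`, `"CS"`, `"RFF"`, `"XV"`.
#' @slot scores numeric score per feature (higher is better for all four
#'   methods implemented here).
#' @slot order integer permutation of all feature indices, sorted by
#'   descending score with ties broken by ascending feature index.
#' @slot featureNames character vector parallel to `scores`.
#' @export
setClass("RankedList",
  representation(
    method       = "character",
    scores       = "numeric",
    order        = "integer",
    featureNames = "character"
  )
)

setValidity("RankedList", function(object) {
  msg <- character()
  if (length(object@method) != 1L ||
      !object@method %in% c("MI", "CS", "RFF", "XV"))
    msg <- c(msg, "method must be one of 'MI', 'CS', 'RFF', 'XV'")
  p <- length(object@scores)
  if (!identical(sort(object@order), seq_len(p)))
    msg <- c(msg, "'order' must be a permutation of all feature indices")
  if (length(object@featureNames) != p)
    msg <- c(msg, "'featureNames' must be parallel to 'scores'")
  s <- object@scores[object@order]
  if (p > 1L && any(diff(s) > 1e-12))
    msg <- c(msg, "'order' must sort scores in descending order")
  if (length(msg)) msg else TRUE
})

#' StageResult: an ordered subset with its prefix-accuracy trace
#'
#' Result of plateau-based truncation of a ranked feature list: the ordered
#' candidate features, the cross-validated accuracy of every evaluated
#' prefix size, and the selected size -- the smallest prefix attaining the
#' maximum accuracy over all evaluated sizes.
#'
#' @slot orderedFeatures integer vector of feature indices, best first.
#' @slot selectedSize single integer, the chosen prefix length.
#' @slot trace data.frame with columns `size` and `accuracy`, one row per
#'   evaluated prefix, in increasing size order.
#' @export
setClass("StageResult",
  representation(
    orderedFeatures = "integer",
    selectedSize    = "integer",
    trace           = "data.frame"
  )
)

setValidity("StageResult", function(object) {
  msg <- character()
  k <- object@selectedSize
  if (length(k) != 1L || k < 1L || k > length(object@orderedFeatures))
    msg <- c(msg, "'selectedSize' must lie in [1, length(orderedFeatures)]")
  tr <- object@trace
  if (!all(c("size", "accuracy") %in% names(tr)))
    msg <- c(msg, "'trace' needs columns 'size' and 'accuracy'")
  else {
    best <- max(tr$accuracy)
    att <- tr$size[tr$accuracy >= best - 1e-12]
    if (length(att) && k != min(att))
      msg <- c(msg, "'selectedSize' must be the smallest size attaining the maximum accuracy")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: pairwise and feature-to-class Pearson correlations
#'
#' @slot r symmetric numeric matrix of pairwise Pearson coefficients over
#'   the supplied features (in the supplied order).  Correlations involving
#'   a constant feature are defined as 0.
#' @slot classR numeric vector of each feature's Pearson correlation with
#'   the integer-encoded class.
#' @slot features integer indices of the features, in the order the matrix
#'   rows/columns use.
#' @slot featureNames character vector parallel to `features`.
#' @export
setClass("CorrelationResult",
  representation(
    r            = "matrix",
    classR       = "numeric",
    features     = "integer",
    featureNames = "character"
  )
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  p <- length(object@features)
  if (!identical(dim(object@r), c(p, p)))
    msg <- c(msg, "'r' must be square over the supplied features")
  else {
    if (max(abs(object@r - t(object@r))) > 1e-10)
      msg <- c(msg, "'r' must be symmetric")
    if (any(abs(object@r) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  if (length(object@classR) != p)
    msg <- c(msg, "'classR' must be parallel to 'features'")
  if (length(msg)) msg else TRUE
})

#' PruneResult: outcome of correlation-based redundancy pruning
#'
#' @slot kept integer feature indices that survived, in the input rank order.
#' @slot discarded data.frame audit trail with columns `discarded`,
#'   `retained` (feature indices) and `r` (the offending correlation).
#' @slot threshold the |r| threshold used.
#' @export
setClass("PruneResult",
  representation(
    kept      = "integer",
    discarded = "data.frame",
    threshold = "numeric"
  )
)

setValidity("PruneResult", function(object) {
  msg <- character()
  if (!all(c("discarded", "retained", "r") %in% names(object@discarded)))
    msg <- c(msg, "'discarded' needs columns 'discarded', 'retained', 'r'")
  else if (length(intersect(object@kept, object@discarded$discarded)))
    msg <- c(msg, "a feature cannot be both kept and discarded")
  if (length(msg)) msg else TRUE
})

#' WOAConfig: configuration of the binary Whale Optimization Algorithm
#'
#' Defaults follow the published schedule for gene-expression benchmarks:
#' 100 iterations, 50 search agents, KNN with 5 neighbours and 10-fold
#' stratified cross-validation for the fitness, 20 repeated runs, a fitness
#' weight of 0.99 on the error term, and a unit spiral shape constant.
#'
#' @slot nAgents number of whales (search agents).
#' @slot maxIter maximum number of iterations per run.
#' @slot spiralB logarithmic-spiral shape constant b.
#' @slot alpha fitness weight in (0,1) on the classification-error term;
#'   1 - alpha weighs the relative subset size.
#' @slot knnK neighbours used by the wrapped KNN classifier.
#' @slot cvFolds stratified cross-validation folds for the fitness.
#' @slot nRuns independent repetitions for [runWOARepeated()].
#' @slot seed master seed; every random draw in a run derives from it.
#' @export
setClass("WOAConfig",
  representation(
    nAgents = "integer", maxIter = "integer", spiralB = "numeric",
    alpha = "numeric", knnK = "integer", cvFolds = "integer",
    nRuns = "integer", seed = "integer"
  )
)

setValidity("WOAConfig", function(object) {
  msg <- character()
  if (object@nAgents < 1L) msg <- c(msg, "'nAgents' must be positive")
  if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be positive")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must lie in (0, 1)")
  if (object@knnK < 1L) msg <- c(msg, "'knnK' must be positive")
  if (object@cvFolds < 2L) msg <- c(msg, "'cvFolds' must be at least 2")
  if (object@nRuns < 1L) msg <- c(msg, "'nRuns' must be at least 1")
  if (length(msg)) msg else TRUE
})

#' SubsetSolution: one evaluated feature subset
#'
#' @slot mask logical vector over the candidate features.
#' @slot accuracy stratified cross-validated KNN accuracy of the subset.
#' @slot fitness minimized objective: alpha * (1 - accuracy) +
#'   (1 - alpha) * size / dim.
#' @slot size number of selected features.
#' @export
setClass("SubsetSolution",
  representation(
    mask = "logical", accuracy = "numeric",
    fitness = "numeric", size = "integer"
  )
)

setValidity("SubsetSolution", function(object) {
  msg <- character()
  if (object@size != sum(object@mask))
    msg <- c(msg, "'size' must equal the number of selected bits")
  if (object@size < 1L)
    msg <- c(msg, "an evaluated solution must select at least one feature")
  if (length(msg)) msg else TRUE
})

#' WOAResult: the leader returned by one WOA run
#'
#' @slot solution the best [SubsetSolution-class] found.
#' @slot candidateFeatures integer indices (into the dataset) of the
#'   features the mask refers to.
#' @slot selectedFeatures integer indices of the selected features.
#' @slot convergence numeric vector of the leader fitness after each
#'   iteration (non-increasing).
#' @slot seed the seed this run used.
#' @export
setClass("WOAResult",
  representation(
    solution          = "SubsetSolution",
    candidateFeatures = "integer",
    selectedFeatures  = "integer",
    convergence       = "numeric",
    seed              = "integer"
  )
)

#' WOASummary: repeated WOA runs with averaged accuracy and subset size
#'
#' @slot runs list of [WOAResult-class], one per repetition.
#' @slot meanAccuracy arithmetic mean of the per-run leader accuracies.
#' @slot meanSize arithmetic mean of the per-run subset sizes.
#' @export
setClass("WOASummary",
  representation(
    runs = "list", meanAccuracy = "numeric", meanSize = "numeric"
  )
)

#' EvaluationReport: pooled stratified cross-validation metrics
#'
#' @slot accuracy,precision,recall,f1 pooled-prediction metrics in `[0, 1]`.
#' @slot perFoldAccuracy numeric accuracy per fold.
#' @slot classifier the classifier specification used.
#' @slot folds number of folds.
#' @slot seed fold-assignment seed.
#' @slot positiveClass label treated as positive for precision/recall
#'   (binary problems), or `"macro"` for macro-averaged multiclass metrics.
#' @export
setClass("EvaluationReport",
  representation(
    accuracy = "numeric", precision = "numeric", recall = "numeric",
    f1 = "numeric", perFoldAccuracy = "numeric", classifier = "character",
    folds = "integer", seed = "integer", positiveClass = "character"
  )
)

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot informative integer column indices of the class-informative
#'   features.
#' @slot groups named list mapping each informative index to the integer
#'   indices of its redundant copies.
#' @slot noise integer indices of the class-independent noise features.
#' @export
setClass("GroundTruth",
  representation(
    informative = "integer", groups = "list", noise = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  copies <- unlist(object@groups, use.names = FALSE)
  all3 <- c(object@informative, copies, object@noise)
  if (anyDuplicated(all3))
    msg <- c(msg, "informative, redundant and noise indices must be disjoint")
  if (length(object@groups) != length(object@informative))
    msg <- c(msg, "'groups' must have one entry per informative feature")
  if (length(msg)) msg else TRUE
})

#' PipelineReport: artifacts of one full tri-stage run
#'
#' @slot rankings list of four [RankedList-class] (MI, CS, RFF, XV).
#' @slot unionFeatures integer indices of the pooled top-m union.
#' @slot featureScores data.frame of per-feature single-feature classifier
#'   accuracies (columns `feature`, `featureName`, `knn`, `svm`, `nb`,
#'   `mean`).
#' @slot stage1 [StageResult-class] of the Phase-1 truncation (size k).
#' @slot correlations [CorrelationResult-class] over the Stage-1 selection.
#' @slot prune [PruneResult-class] redundancy-pruning audit.
#' @slot stage2 [StageResult-class] of the Phase-2 truncation (size j).
#' @slot woa [WOASummary-class] of the repeated wrapper runs.
#' @slot featureNames all feature names of the input dataset.
#' @slot params named list echoing the pipeline parameters.
#' @slot seed master seed.
#' @export
setClass("PipelineReport",
  representation(
    rankings      = "list",
    unionFeatures = "integer",
    featureScores = "data.frame",
    stage1        = "StageResult",
    correlations  = "CorrelationResult",
    prune         = "PruneResult",
    stage2        = "StageResult",
    woa           = "WOASummary",
    featureNames  = "character",
    params        = "list",
    seed          = "integer"
  )
)
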