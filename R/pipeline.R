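#' Default union prefix length for a given feature count
#'
#' Mirrors the published per-dataset settings, which grow with the width of
#' the table: 50 for up to 1000 features, 100 up to 6000, 150 up to 10000,
#' and 250 beyond, never exceeding the feature count itself.
#'
#' @param p number of features.
#' @return an integer prefix length m.
#' @export
defaultUnionSize <- function(p) {
  m <- if (p <= 1000L) 50L else if (p <= 6000L) 100L
       else if (p <= 10000L) 150L else 250L
  min(m, as.integer(p))
}

#' Run the full tri-stage feature-selection pipeline
#'
#' Executes, in order: class-wise mean imputation (when missing cells are
#' present), standardize-then-normalize preprocessing, the four filter
#' rankings (MI, CS, RFF, XV), the top-m union, per-feature scoring with
#' KNN/SVM/NB under shared folds, accuracy sorting, plateau truncation to
#' the top k (XGBoost, 10-fold CV), Pearson-correlation redundancy pruning
#' at the |r| threshold, plateau truncation to the top j, and finally the
#' repeated binary Whale Optimization wrapper on the j survivors.  Every
#' stochastic component (fold assignments, XGBoost, WOA) is driven by
#' sub-seeds derived from `seed`, so identical inputs give byte-identical
#' reports.
#'
#' @param x an [FSDataset-class], or a file path passed to [readTabular()].
#' @param labelColumn label column name (only used when `x` is a path).
#' @param unionSize top-m prefix per ranking; `NULL` (default) picks
#'   [defaultUnionSize()] for the dataset width.
#' @param nBins discretization bins for the MI and CS filters (default 10).
#' @param relieffK ReliefF neighbours (default 10).
#' @param coarseStep plateau coarse stride (default 5).
#' @param cvFolds stratified folds for all evaluations (default 10).
#' @param pccThreshold redundancy threshold on |r| (default 0.7).
#' @param woa a [WOAConfig-class] for the wrapper stage; its `seed` slot is
#'   overridden by a sub-seed of `seed`.
#' @param relabel optional named character vector mapping original labels
#'   to new ones (e.g. collapsing multiclass codes to affected/unaffected)
#'   applied before anything else.
#' @param seed master seed.
#' @return a [PipelineReport-class].
#' @export
runPipeline <- function(x, labelColumn = "class", unionSize = NULL,
                        nBins = 10L, relieffK = 10L, coarseStep = 5L,
                        cvFolds = 10L, pccThreshold = 0.7,
                        woa = woaConfig(), relabel = NULL, seed = 1L) {
  if (is.character(x)) x <- readTabular(x, labelColumn)
  stopifnot(is(x, "FSDataset"))
  if (!is.null(relabel)) {
    y <- as.character(classLabels(x))
    hit <- y %in% names(relabel)
    y[hit] <- relabel[y[hit]]
    x <- FSDataset(featureMatrix(x), y, missingMask = missingMask(x))
  }
  p <- nFeatures(x)
  if (is.null(unionSize)) unionSize <- defaultUnionSize(p)
  if (unionSize > p)
    stop("'unionSize' exceeds the feature count (", p, ")")

  seeds <- deriveSeeds(seed, 4L)

  message("[preprocess] ", nSamples(x), " samples x ", p, " features")
  if (anyNA(featureMatrix(x))) x <- imputeClasswiseMean(x)
  x <- standardizeNormalize(x)

  message("[stage 1] filter rankings + top-", unionSize, " union")
  rankings <- list(rankMutualInformation(x, nBins),
                   rankChiSquare(x, nBins),
                   rankReliefF(x, relieffK),
                   rankXVariance(x))
  union <- unionTopM(rankings, unionSize)
  message("[stage 1] scoring ", length(union), " union features individually")
  recs <- scoreFeaturesIndividually(x, union, cvFolds, seeds[1L],
                                    knnK = woa@knnK)
  ord <- sortByMeanAccuracy(recs)
  stage1 <- plateauSelect(x, ord, coarseStep, cvFolds, seeds[2L])
  message("[stage 1] k = ", selectedSize(stage1))

  message("[stage 2] correlation pruning at |r| > ", pccThreshold)
  s1feats <- selectedFeatures(stage1)
  if (length(s1feats) >= 2L) {
    cm <- featureCorrelations(x, s1feats)
    pr <- pruneCorrelated(cm, pccThreshold)
  } else {
    cm <- new("CorrelationResult", r = matrix(1, 1, 1), classR = 0,
              features = as.integer(s1feats),
              featureNames = featureNames(x)[s1feats])
    pr <- new("PruneResult", kept = as.integer(s1feats),
              discarded = data.frame(discarded = integer(),
                                     retained = integer(), r = numeric()),
              threshold = pccThreshold)
  }
  stage2 <- selectTopJ(x, keptFeatures(pr), coarseStep, cvFolds, seeds[3L])
  message("[stage 2] ", nrow(discardAudit(pr)), " discarded, j = ",
          selectedSize(stage2))

  message("[stage 3] binary WOA, ", woa@nRuns, " runs x ", woa@maxIter,
          " iterations")
  woa@seed <- as.integer(seeds[4L])
  summ <- runWOARepeated(x, selectedFeatures(stage2), woa)
  message(sprintf("[stage 3] mean accuracy %.4f, mean size %.2f",
                  summ@meanAccuracy, summ@meanSize))

  new("PipelineReport",
      rankings = rankings, unionFeatures = union, featureScores = recs,
      stage1 = stage1, correlations = cm, prune = pr, stage2 = stage2,
      woa = summ, featureNames = featureNames(x),
      params = list(unionSize = unionSize, nBins = nBins,
                    relieffK = relieffK, coarseStep = coarseStep,
                    cvFolds = cvFolds, pccThreshold = pccThreshold,
                    nAgents = woa@nAgents, maxIter = woa@maxIter,
                    knnK = woa@knnK, alpha = woa@alpha, nRuns = woa@nRuns),
      seed = as.integer(seed))
}

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport (seed ", object@seed, ")\n", sep = "")
  cat(" union m      :", object@params$unionSize,
      "-> union size", length(object@unionFeatures), "\n")
  cat(" stage 1 k    :", selectedSize(object@stage1), "\n")
  cat(" discarded    :", nrow(discardAudit(object@prune)), "\n")
  cat(" stage 2 j    :", selectedSize(object@stage2), "\n")
  cat(sprintf(" WOA          : mean accuracy %.4f, mean size %.2f over %d runs\n",
              object@woa@meanAccuracy, object@woa@meanSize,
              length(object@woa@runs)))
  invisible(NULL)
})

#' Serialize a pipeline report to JSON
#'
#' Writes every stage's artifact -- the union, the per-feature accuracy
#' records, both plateau traces and selected sizes, the discard audit
#' trail, the per-run wrapper solutions and their means -- as one JSON
#' document.  The same report always serializes to the same bytes.
#'
#' @param report a [PipelineReport-class].
#' @param path output path, or `NULL` to return the JSON string.
#' @return the JSON string, invisibly when written to `path`.
#' @export
reportJSON <- function(report, path = NULL) {
  fn <- report@featureNames
  stage <- function(sr) list(
    ordered_features = fn[orderedFeatures(sr)],
    selected_size = selectedSize(sr),
    selected_features = fn[selectedFeatures(sr)],
    prefix_accuracy_trace = accuracyTrace(sr))
  audit <- discardAudit(report@prune)
  obj <- list(
    schema = "tristagefs-report-1",
    seed = report@seed,
    params = report@params,
    filter_scores = lapply(report@rankings, function(r) list(
      method = rankMethod(r),
      top = fn[utils::head(featureOrder(r), report@params$unionSize)])),
    union_features = fn[report@unionFeatures],
    feature_scores = report@featureScores,
    stage1 = stage(report@stage1),
    prune = list(
      threshold = report@prune@threshold,
      kept = fn[keptFeatures(report@prune)],
      discarded = data.frame(discarded = fn[audit$discarded],
                             retained = fn[audit$retained],
                             r = audit$r)),
    stage2 = stage(report@stage2),
    woa = list(
      mean_accuracy = report@woa@meanAccuracy,
      mean_size = report@woa@meanSize,
      runs = lapply(report@woa@runs, function(r) list(
        seed = r@seed,
        selected_features = fn[r@selectedFeatures],
        accuracy = r@solution@accuracy,
        size = r@solution@size,
        fitness = r@solution@fitness)))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
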