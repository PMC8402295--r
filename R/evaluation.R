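#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that every class is spread as
#' evenly as possible across folds.  The assignment is a deterministic
#' function of `(labels, k, seed)`.
#'
#' @param labels factor of class labels.
#' @param k number of folds, at least 2.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  if (k < 2L) stop("'k' must be at least 2")
  tab <- table(labels)
  if (any(tab < k))
    stop("stratification infeasible: every class needs at least ", k,
         " samples")
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

# Deterministic k-nearest-neighbour prediction from raw matrices.
# Squared Euclidean distance; neighbour ties broken by ascending training
# index, vote ties by earliest class level.
knnPredict <- function(trainX, trainY, testX, k) {
  k <- min(k, nrow(trainX))
  lv <- levels(trainY)
  yi <- as.integer(trainY)
  pred <- integer(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    d <- colSums((t(trainX) - testX[i, ])^2)
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- tabulate(yi[nb], nbins = length(lv))
    pred[i] <- which.max(votes)
  }
  factor(lv[pred], levels = lv)
}

# Same, but from a precomputed full squared-distance matrix (rows/cols over
# all samples). Used heavily by the wrapper fitness.
knnPredictFromDist <- function(D, labels, trainIdx, testIdx, k) {
  k <- min(k, length(trainIdx))
  lv <- levels(labels)
  yi <- as.integer(labels)[trainIdx]
  pred <- integer(length(testIdx))
  for (j in seq_along(testIdx)) {
    d <- D[testIdx[j], trainIdx]
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- tabulate(yi[nb], nbins = length(lv))
    pred[j] <- which.max(votes)
  }
  factor(lv[pred], levels = lv)
}

majorityLevel <- function(y) {
  lv <- levels(y)
  factor(lv[which.max(tabulate(as.integer(y), nbins = length(lv)))],
         levels = lv)
}

# Fit a classifier on (trainX, trainY) and predict testX.
# spec: "knn", "svm", "nb" or "xgb"; opts carries knnK / nrounds / seed.
# Zero-variance training columns are dropped for svm/nb (they carry no
# information and break the underlying fits); if nothing remains the
# majority training class is predicted.
fitPredict <- function(trainX, trainY, testX, spec, opts = list()) {
  trainY <- droplevels(trainY)
  if (nlevels(trainY) < 2L)
    return(factor(rep(levels(trainY), nrow(testX)), levels = levels(trainY)))
  if (spec == "knn") {
    k <- if (is.null(opts$knnK)) 5L else opts$knnK
    return(knnPredict(trainX, trainY, testX, k))
  }
  if (spec %in% c("svm", "nb")) {
    keep <- apply(trainX, 2L, function(v) stats::var(v) > 0)
    if (!any(keep)) {
      maj <- majorityLevel(trainY)
      return(factor(rep(as.character(maj), nrow(testX)),
                    levels = levels(trainY)))
    }
    trX <- trainX[, keep, drop = FALSE]
    teX <- testX[, keep, drop = FALSE]
    if (spec == "svm") {
      fit <- e1071::svm(trX, trainY)
      return(stats::predict(fit, teX))
    }
    fit <- e1071::naiveBayes(trX, trainY)
    return(stats::predict(fit, teX))
  }
  if (spec == "xgb") {
    nrounds <- if (is.null(opts$nrounds)) 30L else opts$nrounds
    seed <- if (is.null(opts$seed)) 1L else opts$seed
    ylab <- as.integer(trainY) - 1L
    nc <- nlevels(trainY)
    params <- if (nc == 2L) {
      xgboost::xgb.params(objective = "binary:logistic", nthread = 1,
                          seed = seed)
    } else {
      xgboost::xgb.params(objective = "multi:softmax", num_class = nc,
                          nthread = 1, seed = seed)
    }
    fit <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(trainX, label = ylab, nthread = 1),
      nrounds = nrounds, verbose = 0)
    p <- stats::predict(fit, xgboost::xgb.DMatrix(testX, nthread = 1))
    cls <- if (nc == 2L) as.integer(p > 0.5) else as.integer(p)
    return(factor(levels(trainY)[cls + 1L], levels = levels(trainY)))
  }
  stop("unknown classifier spec: ", spec)
}

# Pooled cross-validated predictions for a feature subset.
cvPredict <- function(x, featureIdx, spec, folds, seed, opts = list()) {
  f <- featureMatrix(x)[, featureIdx, drop = FALSE]
  y <- classLabels(x)
  fid <- if (length(folds) > 1L) folds else stratifiedFolds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in sort(unique(fid))) {
    te <- which(fid == k)
    tr <- which(fid != k)
    pred[te] <- fitPredict(f[tr, , drop = FALSE], y[tr],
                           f[te, , drop = FALSE], spec, opts)
  }
  list(pred = pred, folds = fid)
}

binaryPRF <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a feature subset by stratified cross-validation
#'
#' Fits and tests the requested classifier fold by fold with a seeded
#' stratified assignment, pools the out-of-fold predictions, and reports
#' accuracy, precision, recall and F1.  For binary problems precision and
#' recall refer to `positiveClass` (default: the second label in sorted
#' order, conventionally the affected/tumor class); for more than two
#' classes the three metrics are macro-averaged over classes.
#'
#' @param x an [FSDataset-class].
#' @param features integer indices (or logical mask) of the feature subset.
#' @param classifier one of `"knn"`, `"svm"`, `"nb"`, `"xgb"`.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param positiveClass label of the positive class, or `NULL` for the
#'   default.
#' @param opts classifier options (`knnK`, `nrounds`).
#' @return an [EvaluationReport-class].
#' @export
stratifiedCVEvaluate <- function(x, features, classifier, folds = 10L,
                                 seed = 1L, positiveClass = NULL,
                                 opts = list()) {
  if (is.logical(features)) features <- which(features)
  if (length(features) == 0L) stop("empty feature subset")
  y <- classLabels(x)
  res <- cvPredict(x, features, classifier, folds, seed, opts)
  pred <- res$pred
  acc <- mean(pred == y)
  perFold <- vapply(sort(unique(res$folds)), function(k)
    mean(pred[res$folds == k] == y[res$folds == k]), numeric(1))
  if (nlevels(y) == 2L) {
    pos <- if (is.null(positiveClass)) sort(levels(y))[2L] else positiveClass
    prf <- binaryPRF(y, pred, pos)
    posName <- pos
  } else {
    prfs <- vapply(levels(y), function(cl) binaryPRF(y, pred, cl),
                   numeric(3))
    prf <- rowMeans(prfs, na.rm = TRUE)
    posName <- "macro"
  }
  new("EvaluationReport",
      accuracy = acc, precision = unname(prf["precision"]),
      recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
      perFoldAccuracy = perFold, classifier = classifier,
      folds = as.integer(max(res$folds)), seed = as.integer(seed),
      positiveClass = posName)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport [%s, %d-fold CV]\n", object@classifier, object@folds))
  cat(sprintf(
    "accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%% (positive: %s)\n",
    100 * object@accuracy, 100 * object@precision, 100 * object@recall,
    100 * object@f1, object@positiveClass))
  invisible(NULL)
})

#' One-sample t-test (lower tail)
#'
#' Tests whether the mean of `sample` is below `referenceMean`:
#' t = (mean - reference) / (sd / sqrt(n)) with the sample (n-1) standard
#' deviation, and a one-sided lower-tail p-value from Student's t with
#' n - 1 degrees of freedom.  Used to compare a set of competitor
#' accuracies against the accuracy of a proposed method.
#'
#' @param sample numeric vector, length at least 2, non-constant.
#' @param referenceMean the reference value.
#' @return list with `t`, `df` and `p` (one-sided, lower tail).
#' @examples
#' oneSampleTTest(c(82.96, 85.58, 99.02, 74.77, 88.72, 98.68), 94.50)
#' @export
oneSampleTTest <- function(sample, referenceMean) {
  if (length(sample) < 2L) stop("need at least 2 observations")
  if (stats::sd(sample) == 0) stop("zero-variance sample")
  ht <- stats::t.test(sample, mu = referenceMean, alternative = "less")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
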