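test_that("stratified folds balance every class and are seeded", {
  y <- factor(rep(c("a", "b", "c"), times = c(12, 9, 6)))
  f <- stratifiedFolds(y, 3, seed = 7)
  expect_length(f, 27L)
  expect_setequal(unique(f), 1:3)
  for (cl in levels(y)) {
    counts <- table(f[y == cl])
    expect_lte(max(counts) - min(counts), 1L)
  }
  expect_identical(f, stratifiedFolds(y, 3, seed = 7))
  expect_false(identical(f, stratifiedFolds(y, 3, seed = 8)))
  expect_error(stratifiedFolds(y, 7), "at least")
  expect_error(stratifiedFolds(y, 1), "at least 2")
})

test_that("deterministic KNN breaks ties by training index and class level", {
  trainX <- matrix(c(0, 0, 10), 3, 1)
  trainY <- factor(c("b", "a", "a"), levels = c("a", "b"))
  # equidistant neighbours 1 and 2; k = 1 picks training index 1 -> "b"
  p1 <- TriStageFS:::knnPredict(trainX, trainY, matrix(0, 1, 1), k = 1)
  expect_equal(as.character(p1), "b")
  # k = 2: one vote each; earliest level "a" wins
  p2 <- TriStageFS:::knnPredict(trainX, trainY, matrix(0, 1, 1), k = 2)
  expect_equal(as.character(p2), "a")
  # k larger than the training set is clipped
  p3 <- TriStageFS:::knnPredict(trainX, trainY, matrix(0, 1, 1), k = 10)
  expect_equal(as.character(p3), "a")
})

test_that("all four classifiers reach perfect metrics on a separable subset", {
  d <- makeTinyDataset(n = 20, nNoise = 3, seed = 12)
  for (clf in c("knn", "svm", "nb", "xgb")) {
    rep <- stratifiedCVEvaluate(d, 1L, clf, folds = 5, seed = 2,
                                opts = list(knnK = 3))
    expect_equal(rep@accuracy, 1)
    expect_equal(rep@precision, 1)
    expect_equal(rep@recall, 1)
    expect_equal(rep@f1, 1)
    expect_equal(rep@perFoldAccuracy, rep(1, 5))
  }
})

test_that("evaluation reports are deterministic and fold counts honest", {
  d <- makeTinyDataset(n = 24, nNoise = 6, seed = 3)
  feats <- seq_len(nFeatures(d))
  a <- stratifiedCVEvaluate(d, feats, "knn", folds = 4, seed = 9,
                            opts = list(knnK = 3))
  b <- stratifiedCVEvaluate(d, feats, "knn", folds = 4, seed = 9,
                            opts = list(knnK = 3))
  expect_equal(a@accuracy, b@accuracy)
  expect_equal(a@perFoldAccuracy, b@perFoldAccuracy)
  expect_equal(a@folds, 4L)
  # pooled accuracy is the sample-weighted mean of per-fold accuracies;
  # with equal fold sizes (24 / 4) the plain mean
  expect_equal(a@accuracy, mean(a@perFoldAccuracy))
  expect_error(stratifiedCVEvaluate(d, integer(), "knn"), "empty")
})

test_that("binary positive class defaults to the second sorted label", {
  y <- rep(c("tumor", "normal"), each = 10)
  set.seed(1)
  d <- FSDataset(cbind(f = as.numeric(y == "tumor") + rnorm(20, 0, 0.01),
                       g = rnorm(20)), y)
  rep <- stratifiedCVEvaluate(d, 1L, "knn", folds = 5, seed = 1,
                              opts = list(knnK = 3))
  expect_equal(rep@positiveClass, "tumor")
  rep2 <- stratifiedCVEvaluate(d, 1L, "knn", folds = 5, seed = 1,
                               positiveClass = "normal",
                               opts = list(knnK = 3))
  expect_equal(rep2@positiveClass, "normal")
})

test_that("multiclass metrics are macro-averaged", {
  y <- rep(c("a", "b", "c"), each = 8)
  set.seed(2)
  d <- FSDataset(cbind(f = as.integer(factor(y)) + rnorm(24, 0, 0.01),
                       g = rnorm(24)), y)
  rep <- stratifiedCVEvaluate(d, 1L, "knn", folds = 4, seed = 3,
                              opts = list(knnK = 3))
  expect_equal(rep@positiveClass, "macro")
  expect_equal(rep@accuracy, 1)
  expect_equal(rep@f1, 1)
})

test_that("the one-sample lower-tail t-test reproduces published rows", {
  # six competitor accuracies against the proposed method's accuracy
  arr <- oneSampleTTest(c(82.96, 85.58, 99.02, 74.77, 88.72, 98.68), 94.50)
  expect_equal(arr$t, -1.618637, tolerance = 1e-6)
  expect_equal(arr$p, 0.083225, tolerance = 1e-4)
  expect_equal(arr$df, 5)
  leu <- oneSampleTTest(c(91.05, 87.5, 90.88, 99.86, 95.45, 100), 100)
  expect_equal(leu$t, -2.790643, tolerance = 1e-6)
  expect_equal(leu$p, 0.019208, tolerance = 1e-4)
  pro <- oneSampleTTest(c(94.17, 100, 91.2, 99.48, 76.47, 98), 100)
  expect_equal(pro$t, -1.871934, tolerance = 1e-6)
  expect_equal(pro$p, 0.060057, tolerance = 1e-4)
})

test_that("t-test algebraic properties hold", {
  s <- c(1, 2, 3, 4, 5)
  # mean equals reference: t = 0, lower-tail p = 0.5
  r0 <- oneSampleTTest(s, mean(s))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  # shifting the reference up makes t more negative and p smaller
  rUp <- oneSampleTTest(s, mean(s) + 1)
  expect_lt(rUp$t, 0)
  expect_lt(rUp$p, 0.5)
  # antisymmetry of t around the mean
  rDn <- oneSampleTTest(s, mean(s) - 1)
  expect_equal(rDn$t, -rUp$t, tolerance = 1e-12)
  expect_equal(rDn$p, 1 - rUp$p, tolerance = 1e-12)
  # scale invariance of t
  rScaled <- oneSampleTTest(10 * s, 10 * (mean(s) + 1))
  expect_equal(rScaled$t, rUp$t, tolerance = 1e-12)
  # hand value: t = (mean - mu) / (sd / sqrt(n))
  expect_equal(rUp$t, -1 / (stats::sd(s) / sqrt(5)), tolerance = 1e-12)
  expect_error(oneSampleTTest(c(1), 0), "at least 2")
  expect_error(oneSampleTTest(c(2, 2, 2), 0), "zero-variance")
})
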