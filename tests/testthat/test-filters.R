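test_that("equal-frequency discretization bins by sorted order with shared ties", {
  expect_equal(discretizeEqualFreq(c(1, 2, 3, 4), 2), c(0L, 0L, 1L, 1L))
  expect_equal(discretizeEqualFreq(rep(3.3, 5), 4), rep(0L, 5))
  expect_equal(discretizeEqualFreq(c(5, 1, 3, 2, 4, 6), 3),
               c(2L, 0L, 1L, 0L, 1L, 2L))
  # identical values always share a bin
  b <- discretizeEqualFreq(c(1, 1, 1, 1, 2, 3), 3)
  expect_length(unique(b[1:4]), 1L)
  expect_error(discretizeEqualFreq(numeric(0), 2), "empty")
  expect_error(discretizeEqualFreq(1:5, 1), "at least 2")
})

test_that("mutual information matches entropy identities and known values", {
  # binary feature identical to a balanced binary class: exactly 1 bit
  y <- rep(c("a", "b"), each = 10)
  d <- FSDataset(cbind(f = as.numeric(y == "b"), g = rep(c(0, 1), 10)), y)
  rl <- rankMutualInformation(d, nBins = 2)
  expect_equal(unname(scores(rl)[1]), 1)
  # feature with identical distribution within each class: MI exactly 0
  expect_equal(unname(scores(rl)[2]), 0)
  # joint counts [[2,1],[1,2]] over 6 samples vs the entropy-identity oracle
  v <- c(0, 0, 1, 0, 1, 1)
  yy <- rep(c("a", "b"), each = 3)
  d2 <- FSDataset(cbind(f = v, pad = c(1, 2, 3, 4, 5, 6)), yy)
  got <- unname(scores(rankMutualInformation(d2, nBins = 2))[1])
  bins <- discretizeEqualFreq(v, 2)
  expect_equal(unname(table(bins, yy)[1, ]), c(2L, 1L), ignore_attr = TRUE)
  expect_equal(got, oracleMI(bins, yy), tolerance = 1e-12)
})

test_that("chi-square matches direct cell summation and known values", {
  # perfectly dependent 2x2 with uniform margins: statistic 20
  y <- rep(c("a", "b"), each = 10)
  d <- FSDataset(cbind(f = as.numeric(y == "b"), g = rep(c(0, 1), 10)), y)
  rl <- rankChiSquare(d, nBins = 2)
  expect_equal(unname(scores(rl)[1]), 20)
  # observed equals expected: statistic 0
  expect_equal(unname(scores(rl)[2]), 0)
  # arbitrary table vs explicit double-loop oracle and stats::chisq.test
  tab <- matrix(c(3, 2, 1, 4), 2, 2)
  expect_equal(TriStageFS:::chisqFromTable(tab),
               unname(suppressWarnings(
                 stats::chisq.test(tab, correct = FALSE)$statistic)),
               tolerance = 1e-12)
})

test_that("table-level MI and chi-square helpers agree with oracles on random tables", {
  set.seed(42)
  for (i in 1:25) {
    bins <- sample.int(sample(2:6, 1), 30, replace = TRUE)
    y <- factor(sample(letters[1:sample(2:4, 1)], 30, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    tab <- table(bins, y)
    expect_equal(TriStageFS:::miFromTable(tab), oracleMI(bins, y),
                 tolerance = 1e-12)
    expect_equal(TriStageFS:::chisqFromTable(tab), oracleChisq(bins, y),
                 tolerance = 1e-12)
  }
})

test_that("ReliefF weights behave as the update rule dictates", {
  # fixed 10-sample configuration: two well-separated clusters by class on
  # 'sep', uniform noise on 'noise', a constant, and a duplicate of 'sep'
  set.seed(3)
  y <- rep(c("a", "b"), each = 5)
  sep <- c(runif(5, 0, 0.1), runif(5, 0.9, 1))
  noise <- runif(10)
  m <- cbind(sep = sep, noise = noise, const = rep(0.4, 10), dup = sep)
  d <- FSDataset(m, y)
  rl <- rankReliefF(d, kNeighbors = 3)
  w <- scores(rl)
  expect_gt(w["sep"], w["noise"])
  expect_equal(unname(w["const"]), 0)
  expect_equal(unname(w["sep"]), unname(w["dup"]), tolerance = 1e-12)
  expect_error(rankReliefF(d, kNeighbors = 5), "more than")
})

test_that("ReliefF is invariant to sample order under full sampling", {
  d <- makeTinyDataset(n = 16, nNoise = 3, seed = 9)
  perm <- sample(seq_len(16))
  d2 <- FSDataset(featureMatrix(d)[perm, ], classLabels(d)[perm])
  expect_equal(scores(rankReliefF(d, kNeighbors = 3)),
               scores(rankReliefF(d2, kNeighbors = 3)), tolerance = 1e-12)
})

test_that("Xvariance sums within-class sample variances", {
  m <- cbind(zero = c(0, 0, 1, 1),
             mix = c(0, 2, 10, 14),
             shift = c(0, 2, 10, 14) + 100)
  d <- FSDataset(m, c("A", "A", "B", "B"))
  s <- scores(rankXVariance(d))
  expect_equal(unname(s["zero"]), 0)
  expect_equal(unname(s["mix"]), 2 + 8)
  # shift invariance
  expect_equal(unname(s["shift"]), unname(s["mix"]), tolerance = 1e-12)
  # oracle agreement on random data
  set.seed(5)
  v <- rnorm(12)
  y <- rep(c("a", "b", "c"), 4)
  d2 <- FSDataset(cbind(v = v, w = runif(12)), y)
  expect_equal(unname(scores(rankXVariance(d2))["v"]), oracleXV(v, y),
               tolerance = 1e-12)
})

test_that("rankings are full permutations ordered by descending score", {
  d <- makeTinyDataset(n = 24, nNoise = 6, seed = 11)
  for (rl in list(rankMutualInformation(d), rankChiSquare(d),
                  rankReliefF(d, 3), rankXVariance(d))) {
    expect_setequal(featureOrder(rl), seq_len(nFeatures(d)))
    s <- scores(rl)[featureOrder(rl)]
    expect_true(all(diff(s) <= 1e-12))
  }
  # MI and chi-square are non-negative
  expect_true(all(scores(rankMutualInformation(d)) >= 0))
  expect_true(all(scores(rankChiSquare(d)) >= 0))
})

test_that("ranking ties break by ascending feature index", {
  d <- makeTinyDataset(n = 10, nNoise = 2, seed = 2)
  m <- cbind(featureMatrix(d), dup = featureMatrix(d)[, "sep"])
  d2 <- FSDataset(m, classLabels(d))
  rl <- rankMutualInformation(d2, nBins = 2)
  sepIdx <- which(featureNames(d2) == "sep")
  dupIdx <- which(featureNames(d2) == "dup")
  expect_lt(which(featureOrder(rl) == sepIdx),
            which(featureOrder(rl) == dupIdx))
})
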