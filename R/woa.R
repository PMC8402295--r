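#' Construct a WOAConfig
#'
#' @param nAgents number of search agents (whales); published runs use 50
#'   to 70 depending on the dataset.
#' @param maxIter iterations per run (default 100).
#' @param spiralB spiral shape constant b (default 1).
#' @param alpha fitness weight on the error term (default 0.99, making the
#'   size penalty a tie-breaker among equally accurate subsets).
#' @param knnK neighbours of the wrapped KNN (4 or 5 in the published
#'   schedule; default 5).
#' @param cvFolds stratified folds for the fitness (default 10).
#' @param nRuns repetitions for [runWOARepeated()] (default 20).
#' @param seed master seed.
#' @return a [WOAConfig-class].
#' @export
woaConfig <- function(nAgents = 50L, maxIter = 100L, spiralB = 1,
                      alpha = 0.99, knnK = 5L, cvFolds = 10L,
                      nRuns = 20L, seed = 1L) {
  new("WOAConfig", nAgents = as.integer(nAgents),
      maxIter = as.integer(maxIter), spiralB = spiralB, alpha = alpha,
      knnK = as.integer(knnK), cvFolds = as.integer(cvFolds),
      nRuns = as.integer(nRuns), seed = as.integer(seed))
}

setMethod("show", "WOAConfig", function(object) {
  cat(sprintf(
    "WOAConfig: %d agents, %d iterations, %d runs | KNN k=%d, %d-fold CV | alpha=%.2f, b=%g, seed=%d\n",
    object@nAgents, object@maxIter, object@nRuns, object@knnK,
    object@cvFolds, object@alpha, object@spiralB, object@seed))
  invisible(NULL)
})

#' Linear shrink coefficient schedule
#'
#' The encircling coefficient scale s decreases linearly from 2 at the
#' first iteration to 0 at the last: s = 2 - p * 2 / maxIter.
#'
#' @param p current iteration, in `[0, maxIter]`.
#' @param maxIter maximum number of iterations.
#' @return the scalar s.
#' @examples
#' shrinkCoefficient(50, 100)  # 1
#' @export
shrinkCoefficient <- function(p, maxIter) {
  if (p < 0 || p > maxIter) stop("'p' must lie in [0, maxIter]")
  2 - p * (2 / maxIter)
}

#' One whale position update
#'
#' With probability 1/2 (draw t) the agent follows the bubble-net spiral
#' around the leader: X' = B' * exp(b l) * cos(2 pi l) + X*, with
#' B' = |X* - X| and l uniform on `[-1, 1]`.  Otherwise coefficient vectors
#' K = 2 s v - s and J = 2 v are drawn (v uniform per coordinate) and each
#' coordinate either encircles the leader (X' = X* - K |J X* - X|, where
#' |K| < 1) or explores toward a randomly chosen agent (same form around
#' X_r, where |K| >= 1).  Since s shrinks from 2 to 0 over iterations,
#' exploration fades out in favour of exploitation.
#'
#' Random draws come from R's global RNG stream; `t`, `v` and `l` can be
#' supplied explicitly to reproduce a specific move.
#'
#' @param position numeric vector, the agent's continuous position.
#' @param leader numeric vector, the best position found so far.
#' @param randomAgent numeric vector, a randomly chosen agent's position.
#' @param s shrink coefficient in `[0, 2]` from [shrinkCoefficient()].
#' @param spiralB spiral shape constant.
#' @param t,v,l optional overrides of the random draws (scalar, vector of
#'   `length(position)`, scalar).
#' @return the new continuous position.
#' @export
updateAgent <- function(position, leader, randomAgent, s, spiralB = 1,
                        t = NULL, v = NULL, l = NULL) {
  d <- length(position)
  if (length(leader) != d || length(randomAgent) != d)
    stop("position vectors must share dimension")
  if (is.null(t)) t <- stats::runif(1)
  if (t < 0.5) {
    if (is.null(v)) v <- stats::runif(d)
    K <- 2 * s * v - s
    J <- 2 * v
    encircle <- abs(K) < 1
    ref <- ifelse(encircle, leader, randomAgent)
    B <- abs(J * ref - position)
    ref - K * B
  } else {
    if (is.null(l)) l <- stats::runif(1, -1, 1)
    Bp <- abs(leader - position)
    Bp * exp(spiralB * l) * cos(2 * pi * l) + leader
  }
}

#' Binarize a continuous position into a feature mask
#'
#' Applies the S-shaped (sigmoid) transfer function coordinate-wise and
#' thresholds each selection probability against an independent uniform
#' draw.  An all-zero outcome is repaired by switching on the coordinate
#' with the largest sigmoid value (ties: lowest index), since every
#' evaluated subset must be non-empty.
#'
#' @param position numeric vector.
#' @param u optional override of the uniform draws.
#' @return logical mask of `length(position)`.
#' @export
binarizePosition <- function(position, u = NULL) {
  sg <- 1 / (1 + exp(-position))
  if (is.null(u)) u <- stats::runif(length(position))
  mask <- sg > u
  if (!any(mask)) mask[which.max(sg)] <- TRUE
  mask
}

# Build a fitness evaluator over a fixed candidate set: stratified KNN CV
# accuracy from precomputed per-feature squared-difference matrices, with a
# mask-keyed cache (the swarm revisits masks often once it converges).
makeFitnessEvaluator <- function(x, candidateFeatures, config, foldSeed) {
  f <- featureMatrix(x)[, candidateFeatures, drop = FALSE]
  y <- classLabels(x)
  n <- nrow(f)
  d <- ncol(f)
  fid <- stratifiedFolds(y, config@cvFolds, foldSeed)
  # n^2 x d matrix of squared coordinate differences
  P <- matrix(0, n * n, d)
  for (j in seq_len(d)) P[, j] <- as.vector(outer(f[, j], f[, j], "-")^2)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  alpha <- config@alpha
  k <- config@knnK
  function(mask) {
    key <- rawToChar(as.raw(mask + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    D <- matrix(rowSums(P[, mask, drop = FALSE]), n, n)
    pred <- factor(rep(NA_character_, n), levels = levels(y))
    for (fk in sort(unique(fid))) {
      te <- which(fid == fk)
      pred[te] <- knnPredictFromDist(D, y, which(fid != fk), te, k)
    }
    acc <- mean(pred == y)
    size <- sum(mask)
    fit <- alpha * (1 - acc) + (1 - alpha) * size / d
    out <- new("SubsetSolution", mask = mask, accuracy = acc,
               fitness = fit, size = as.integer(size))
    cache[[key]] <- out
    out
  }
}

#' Evaluate the wrapper fitness of a feature mask
#'
#' Fitness = alpha * (1 - accuracy) + (1 - alpha) * size / dim, where
#' accuracy is the stratified cross-validated KNN accuracy on the masked
#' features and dim the number of candidate features.  Lower is better:
#' with alpha close to 1 the error dominates and the size term breaks ties
#' in favour of smaller subsets.
#'
#' @param x an [FSDataset-class].
#' @param candidateFeatures integer indices of the candidate features the
#'   mask refers to.
#' @param mask logical vector over `candidateFeatures`, at least one `TRUE`.
#' @param config a [WOAConfig-class]; `config@seed` fixes the fold
#'   assignment.
#' @return a [SubsetSolution-class].
#' @export
woaFitness <- function(x, candidateFeatures, mask, config = woaConfig()) {
  if (!any(mask)) stop("empty mask")
  if (length(mask) != length(candidateFeatures))
    stop("'mask' must be parallel to 'candidateFeatures'")
  makeFitnessEvaluator(x, candidateFeatures, config, config@seed)(mask)
}

#' One binary Whale Optimization run
#'
#' Initializes `nAgents` continuous positions uniformly on `[-1, 1]` per
#' coordinate, binarizes and evaluates them, then iterates: for each agent,
#' update the position ([updateAgent()]) with the current shrink
#' coefficient, clip any coordinate beyond the search space to `[-5, 5]`
#' (keeping the sigmoid transfer responsive), binarize, evaluate the
#' fitness, and adopt the agent as leader if it strictly improves.  The
#' leader fitness is therefore non-increasing over iterations.  Everything
#' is driven by `config@seed`: the same dataset, candidates, and config
#' return the identical solution.
#'
#' @param x an [FSDataset-class].
#' @param candidateFeatures integer indices of the candidate features.
#' @param config a [WOAConfig-class].
#' @return a [WOAResult-class].
#' @export
runWOA <- function(x, candidateFeatures, config = woaConfig()) {
  if (length(candidateFeatures) == 0L) stop("no candidate features")
  d <- length(candidateFeatures)
  evalFit <- makeFitnessEvaluator(x, candidateFeatures, config, config@seed)
  withSeed(config@seed, {
    pos <- matrix(stats::runif(config@nAgents * d, -1, 1),
                  config@nAgents, d)
    sols <- apply(pos, 1L, function(p) evalFit(binarizePosition(p)))
    fits <- vapply(sols, function(s) s@fitness, numeric(1))
    bi <- which.min(fits)
    leaderSol <- sols[[bi]]
    leaderPos <- pos[bi, ]
    conv <- numeric(config@maxIter)
    for (p in 0:(config@maxIter - 1L)) {
      s <- shrinkCoefficient(p, config@maxIter)
      for (i in seq_len(config@nAgents)) {
        ri <- sample.int(config@nAgents, 1L)
        newPos <- updateAgent(pos[i, ], leaderPos, pos[ri, ], s,
                              config@spiralB)
        newPos <- pmin(pmax(newPos, -5), 5)
        pos[i, ] <- newPos
        sol <- evalFit(binarizePosition(newPos))
        if (sol@fitness < leaderSol@fitness) {
          leaderSol <- sol
          leaderPos <- newPos
        }
      }
      conv[p + 1L] <- leaderSol@fitness
    }
    new("WOAResult", solution = leaderSol,
        candidateFeatures = as.integer(candidateFeatures),
        selectedFeatures = as.integer(candidateFeatures[leaderSol@mask]),
        convergence = conv, seed = config@seed)
  })
}

#' Repeated WOA runs with averaged accuracy and subset size
#'
#' Performs `config@nRuns` independent [runWOA()] invocations whose seeds
#' derive from the master seed by a fixed splitting rule, and reports the
#' arithmetic means of the per-run leader accuracies and subset sizes
#' alongside every per-run solution.
#'
#' @inheritParams runWOA
#' @return a [WOASummary-class].
#' @export
runWOARepeated <- function(x, candidateFeatures, config = woaConfig()) {
  seeds <- deriveSeeds(config@seed, config@nRuns)
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg@seed <- as.integer(s)
    runWOA(x, candidateFeatures, cfg)
  })
  accs <- vapply(runs, function(r) r@solution@accuracy, numeric(1))
  sizes <- vapply(runs, function(r) r@solution@size, integer(1))
  new("WOASummary", runs = runs, meanAccuracy = mean(accs),
      meanSize = mean(sizes))
}

setMethod("show", "SubsetSolution", function(object) {
  cat(sprintf("SubsetSolution: %d features, accuracy %.4f, fitness %.6f\n",
              object@size, object@accuracy, object@fitness))
  invisible(NULL)
})

setMethod("show", "WOAResult", function(object) {
  cat(sprintf(
    "WOAResult: %d of %d candidates selected | accuracy %.4f, fitness %.6f (seed %d)\n",
    object@solution@size, length(object@candidateFeatures),
    object@solution@accuracy, object@solution@fitness, object@seed))
  invisible(NULL)
})

setMethod("show", "WOASummary", function(object) {
  cat(sprintf(
    "WOASummary: %d runs | mean accuracy %.4f, mean subset size %.2f\n",
    length(object@runs), object@meanAccuracy, object@meanSize))
  invisible(NULL)
})

#' Write a convergence trace to CSV
#'
#' @param result a [WOAResult-class].
#' @param path output path; columns `iteration` (1-based) and
#'   `leader_fitness`.
#' @return `path`, invisibly.
#' @export
writeConvergence <- function(result, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(result@convergence),
               leader_fitness = result@convergence),
    path, row.names = FALSE)
  invisible(path)
}
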