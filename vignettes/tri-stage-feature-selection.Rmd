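---
title: "Tri-stage hybrid filter–wrapper feature selection"
author: "TriStageFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-stage hybrid filter–wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Gene-expression classification tables are extremely wide and short: tens to
a few hundred samples against thousands of measured features, most of them
irrelevant or redundant. Wrapper searches (subset search driven by a
classifier) give the best subsets but are unaffordable on the full width;
filter scores are cheap but blind to feature interactions and redundancy.
TriStageFS implements a three-phase hybrid that uses filters to shrink the
width to something a wrapper can afford, removes redundancy in between, and
only then runs a metaheuristic wrapper.

# Method

## Phase 1 — filter ensemble, union, individual scoring, plateau truncation

Four filter scores are computed per feature and each produces a full
descending ranking (`rankMutualInformation`, `rankChiSquare`,
`rankReliefF`, `rankXVariance`):

* **Mutual information (MI)**, in bits, between the equal-frequency
  discretized feature and the class, via the plug-in estimate on the
  contingency table.
* **Chi-square (CS)**, the Pearson statistic on the same table. Higher
  values indicate stronger dependence and rank better.
* **ReliefF (RFF)**, multiclass, with Manhattan distance on range-normalized
  features, `kNeighbors = 10` by default, deterministic full sampling (every
  sample is a pivot), and miss contributions weighted by class priors.
* **Xvariance (XV)**, the sum over classes of the within-class sample
  variance (denominator n−1). In this framework higher ranks better.

The top `m` of each ranking are pooled by set union
(`unionTopM`). The default `m` follows the published per-dataset schedule
(`defaultUnionSize`): 50 up to 1000 features, 100 up to 6000, 150 up to
10000, 250 beyond.

Every union feature is then scored individually
(`scoreFeaturesIndividually`): its own stratified 10-fold cross-validated
accuracy under KNN, SVM, and naive Bayes, all three sharing one fold
assignment so the comparison is paired. Features are sorted by the mean of
the three accuracies (`sortByMeanAccuracy`), ties broken by ascending
feature index.

The sorted list is truncated at the **plateau** (`plateauSelect`): prefix
sizes are scanned with a coarse stride (default 5) plus the full length,
the neighbourhood of the best coarse size is refined at stride 1, and the
selected size `k` is the *smallest* prefix attaining the maximum prefix
accuracy. Prefix accuracy is the 10-fold cross-validated accuracy of a
gradient-boosted tree ensemble (XGBoost, 30 rounds, single thread for
reproducibility) on the prefix.

**Repeated cross-validation in the plateau.** With 60 samples one 10-fold
split measures accuracy at a granularity of 1/60, and the argmax of a noisy
trace is unstable. The prefix trace is therefore averaged over
`nRepeats = 10` independently seeded stratified fold assignments (shared
across prefix sizes) before the plateau rule is applied. This is a
variance-reduction choice in this implementation; set `nRepeats = 1` to
reproduce a single-split trace.

## Phase 2 — correlation pruning, second truncation

`featureCorrelations` computes the Pearson correlations between the `k`
survivors and between each survivor and the 0/1-encoded class. Constant
features have all correlations defined as 0. `pruneCorrelated` walks the
Phase-1 rank order greedily: for each surviving pair with `|r| > 0.7`
(threshold from the published setup) the member with the smaller `|class_r|`
is discarded (ties: the later-ranked one), and every discard is recorded in
an audit trail (`discardAudit`). The kept list is truncated again by the
same plateau rule (`selectTopJ`), giving `j` features.

## Phase 3 — binary Whale Optimization wrapper

`runWOA` searches subsets of the `j` survivors. Agents hold continuous
positions; per iteration and coordinate the coefficients are

* shrink scale `s = 2 − 2p / maxIter` (`shrinkCoefficient`), linear from 2
  to 0,
* `K = 2 s v − s` and `J = 2 v` with `v` uniform per coordinate,

and each agent either (probability 1/2) follows the logarithmic spiral
around the leader, or moves coordinate-wise toward the leader where
`|K| < 1` (exploitation) and toward a random agent where `|K| ≥ 1`
(exploration). Positions are clipped to `[-5, 5]` to keep the transfer
function responsive, then binarized by a sigmoid transfer against uniform
draws (`binarizePosition`), with an all-zero mask repaired to the single
highest-probability coordinate. The fitness (minimized) is

```
fitness = alpha * (1 - accuracy) + (1 - alpha) * size / dim
```

with `alpha = 0.99`, `accuracy` the stratified 10-fold cross-validated KNN
accuracy of the masked subset, and `dim = j`; the size term breaks ties
among equally accurate subsets in favour of smaller ones. The leader is
replaced only on strict improvement, so the logged convergence trace is
non-increasing. `runWOARepeated` performs 20 runs under derived sub-seeds
and reports per-run solutions plus mean accuracy and mean subset size,
which is how the published experiments report their numbers.

Two encoding choices worth noting: the coefficient draws are per
*coordinate* (some reference implementations draw one scalar per agent
per iteration; either is consistent with the published equations), and the
wrapped KNN is a hand-rolled deterministic implementation — squared
Euclidean distances, neighbour ties broken by ascending training index,
vote ties by the earliest class level — because library KNNs with
randomized tie-breaking destroy run-to-run reproducibility.

# Defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| `unionSize` (m) | width schedule 50/100/150/250 | published per-dataset settings |
| `nBins` | 10 | equal-frequency bins for MI/CS on standardized data |
| `relieffK` | 10 | common ReliefF neighbourhood; full deterministic sampling |
| `coarseStep` | 5 | published coarse stride, refined at ±1 around the best |
| `nRepeats` | 10 | repeated-CV smoothing of the plateau trace (see above) |
| `cvFolds` | 10 | published protocol |
| `pccThreshold` | 0.7 | published redundancy cut on `abs(r)` |
| `nAgents` | 50 | published range 50–70 |
| `maxIter` | 100 | published setting |
| `knnK` | 5 | published settings use 4 or 5 |
| `alpha` | 0.99 | error term dominates; size is a tie-breaker |
| `nRuns` | 20 | published averaging convention |

# Preprocessing

`readTabular` loads CSV or ARFF with `?`/empty cells as missing.
`imputeClasswiseMean` fills each missing cell with the mean of its feature
within its class (falling back to the feature's global mean when a whole
class is missing). `standardizeNormalize` z-scores each feature (n−1
denominator) and then min-max rescales it to [0, 1]; constant features map
to 0.5. Note the preprocessing is computed once on the full table before
cross-validation, as in the published pipeline; strictly leak-free
estimates would refit it inside every training fold, so reported CV
accuracies are optimistic by a (usually small) margin.

# Synthetic data

`syntheticDataset` generates class-conditional normal informative features
(unit variance, class means stepping by `effectSize`), redundant copies
formed as source plus Gaussian noise whose variance is calibrated from the
source's mixture variance so the *population* correlation with the source
is exactly `redundancyRho`, and iid standard-normal noise features;
optional uniform cell knockout exercises imputation. `recoveryScore`
counts a planted group as recovered when the selection contains its source
or any copy. The generator is intentionally simple — normal marginals, no
between-group correlation, balanced classes — and is meant for calibration
and testing, not as a realistic expression simulator.

# Problem sizes and cost

The wrapper fitness precomputes per-feature squared-difference matrices
(O(n² · j) memory) and caches evaluated masks, so a full pipeline on a
60 × 500 table with the default 50 agents × 100 iterations × 20 runs
completes in well under a minute on one CPU. Width is effectively
unlimited for the filter phase (cost linear in features); sample counts in
the thousands make the n² wrapper kernel and ReliefF distance matrix the
bottleneck.

# Worked example

```{r example}
library(TriStageFS)
g <- syntheticDataset(nSamples = 60, nInformative = 5,
                      nRedundantPerInformative = 2, nNoise = 485,
                      effectSize = 1.5, redundancyRho = 0.9, seed = 1)
report <- runPipeline(g$dataset, seed = 1)
report
recoveryScore(selectedFeatures(report@stage2), g$truth)
reportJSON(report, "report.json")
```

# Limitations

* Whole-table standardization before CV (see above) mirrors the published
  protocol but slightly inflates accuracy estimates.
* The plateau rule reacts to CV noise; `nRepeats` mitigates but does not
  remove this at very small n.
* Greedy correlation pruning is order-dependent by design (Phase-1 rank
  order) and does not find a maximum independent set.
* The WOA is a stochastic heuristic; on small candidate sets it reliably
  matches exhaustive enumeration (see the acceptance tests), but no
  optimality guarantee exists in general.
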