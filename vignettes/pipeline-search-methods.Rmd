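---
title: "Evolving tree-based ML pipelines for clinical feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving tree-based ML pipelines for clinical feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binary classification on clinical and metabolomic feature tables — a few
hundred to a thousand patients, on the order of a hundred mixed
continuous/binary features, class imbalance, missing values — rarely comes
down to picking one classifier. The chain of pre-processing decisions
(scaling, feature selection, constructed features) interacts with the
classifier choice, and a hand-tuned or grid-searched single model can be
beaten by an unglamorous classifier sitting on the right stack of
transformations. `pipetree` automates that joint choice: it searches over
*pipelines* represented as expression trees and tuned by genetic
programming, the strategy popularized by tree-based AutoML tools for
exactly this kind of tabular biomedical data.

## The pipeline model

A pipeline is a tree. Leaves are copies of the dataset; internal nodes are
operators — transformers (scalers, binarizer, normalizer, PCA, ICA, kernel
approximations, feature agglomeration), constructors (polynomial features,
zero counts, one-hot encoding, a stacking estimator that appends an
internal classifier's prediction and class probabilities), and selectors
(variance threshold, percentile and family-wise-error F-tests, recursive
feature elimination, select-from-model). Optional combine nodes concatenate
the columns of two branches. The root, always and uniquely, is a
classifier. The full catalog holds 11 classifiers, 14
transformers/constructors and 5 selectors; reduced catalogs keep the full
operator set but a single classifier.

**Complexity** is the count of operator nodes including the classifier, so
a bare grid-searched classifier has complexity 1 and a classifier with four
pre-processors has complexity 5. Combine nodes and dataset leaves are free.

**Fitness** is mean balanced accuracy under stratified k-fold
cross-validation (default 10-fold): the unweighted average of the two
per-class recalls, which equals plain accuracy on balanced data and resists
inflation on imbalanced data. Every operator obeys a strict
fit-on-train/apply-to-anything contract inside each fold, including the
stacking estimator's internal classifier, so no fold ever sees statistics
learned from its own test portion.

## The search

Each generation: (1) the single highest-fitness pipeline is copied into 10%
of the next population — these elite slots are protected from variation,
which makes best-so-far fitness provably non-decreasing when CV folds are
held fixed; (2) the remaining 90% are chosen by three-way tournament with
two-way parsimony — of three random candidates, drop the worst fitness,
then keep the *less complex* of the survivors; (3) one-point crossover is
applied to 10% of the new population and mutation (insert / remove /
substitute an operator, or re-sample one hyperparameter from its finite
domain, uniformly among applicable moves) to 90%. These crossover and
mutation rates are the documented defaults of the reference tool; the paper
trail for the method leaves them user-specified. A Pareto archive of
pipelines non-dominated in (fitness up, complexity down) is maintained
across the run; the reported best is the archive member with maximal
fitness, ties to the simpler tree.

Pipelines that fail to evaluate — a selector that empties the feature set,
multinomial naive Bayes on negative input, a singular transform, or an
intermediate table wider than 1024 columns (a resource guard against
stacked polynomial expansions) — receive sentinel fitness `-Inf` and remain
in the population for selection purposes rather than crashing the run.

Because evolutionary search is stochastic, the representative-model
protocol re-runs the whole search under `n_seeds` different seeds (50 in
the original protocol) and keeps the run whose best pipeline has the
highest CV balanced accuracy.

### Determinism and caching

Every source of randomness — fold assignment, tree generation, variation,
stochastic operators and classifiers — derives from one master seed, and
fold assignment is computed on sorted sample ids, so results are invariant
to row order and bit-reproducible for a fixed seed (when no wall-clock
budget interferes; the time budget is checked between generations, and a
timed-out run returns its archive so far). Within one run, fitness records
are memoized on the serialized tree: evaluation is deterministic given
(tree, folds, seed), so memoization changes nothing but runtime. Partial
(per-subtree) results are never cached.

### Open design points, and how they were resolved

* *Elite replacement*: the single best pipeline is copied into all elite
  slots (the alternative — copying the Pareto front — is noted but not
  used, since the protocol names "the pipeline with the highest fitness").
* *Tournament currency*: tournaments compare raw mean CV balanced accuracy
  with the parsimony step as described, not Pareto rank.
* *Fitness ties at the drop step*: the more complex candidate is dropped,
  consistent with parsimony pressure.
* *Combine nodes* concatenate columns without de-duplication.
* *CV folds* are stratified and fixed for a whole run by default
  (`refold_per_generation` redraws them per generation when variance
  reduction matters more than monotonicity).

## Data handling

Feature tables are numeric matrices with per-feature kinds (continuous,
binary, categorical). Categorical columns are label-encoded at load time
(the one-hot operator is available in the catalog when indicator expansion
helps); binary features are 0/1 by construction. Samples with a missing
label are dropped with a message.

Missing values are imputed once, up front, by k-nearest-neighbour
averaging: distance between two samples is the Euclidean distance over the
features *observed in both*, scaled up by the fraction of usable features;
each missing entry becomes the mean of that feature over the k = 5 nearest
donors observing it. The neighbourhood size and metric are package choices
(the protocol names the KNN strategy but not its parameters) and `k` is
exposed. Imputation is idempotent and never touches observed entries.

The 75/25 train/validation split is stratified (per-class validation
counts are `round(fraction x class size)`, half-away-from-zero, with the
larger class absorbing the rounding remainder so the global count is
exactly `round(fraction x n)`); whether the original study stratified its
split is unstated, so stratification is our documented choice.

## The synthetic cohort

No real cohort ships with the package; the generator emulates the *shape*
of an angiography cohort with NMR metabolomics: 925 samples, 73 correlated
continuous metabolic features (block-correlated Gaussians, block size 5,
within-block correlation 0.6, half the columns exponentiated to a positive
skewed scale), 27 mixed clinical features, a three-level latent severity
(none / non-obstructive / obstructive) binarized as P1 (any disease vs
none) and P2 (obstructive vs rest), 5% MCAR missingness on metabolic
columns only. Class proportions default to (0.20, 0.20, 0.60): the
published cohort's counts are not in the text we derive from, and its high
validation precision at moderate recall implies a disease-majority cohort;
the proportions are configurable and labeled an assumption. Informative
columns get a mean shift of `effect_size x severity` (metabolic) or an
`effect_size`-scaled logit shift (clinical Bernoulli); indices and effect
sizes are returned as ground truth so feature-importance rankings can be
scored by planted-signal recovery.

What the generator does *not* emulate: real NMR covariance, units,
platform artifacts, informative missingness, or feature semantics. Tests
passing on it show the machinery is correct and can find planted structure;
they say nothing about clinical performance on real data.

An `xor_pair` flag adds two binary features whose XOR shifts the severity
logit. Because that severity is sampled through a noisy cumulative-logit
link, the Bayes-optimal balanced accuracy of the planted pair is modest by
construction; the *strong* form of the interaction argument is therefore
demonstrated on the pure XOR generator (`generate_xor_dataset()`): label =
XOR of two balanced binary features plus Gaussian noise columns. Logistic
regression is structurally blind to XOR (CV balanced accuracy ~0.5).
Notably, a single greedily-induced decision tree also fails it (~0.6 even
when grown deep) — the greedy split criterion sees no marginal gain in
either XOR feature — while randomized-split ensembles (extra trees),
polynomial feature construction feeding any classifier, and small MLPs
solve it outright. This is precisely the mechanism that motivates searching
over pipelines rather than tuning one model.

## Numerical choices

* Standard scaler uses the population standard deviation; zero-variance
  features get scale 1 (logged, no division by zero).
* Binarizer is strict `> threshold`; Bernoulli naive Bayes binarizes at
  threshold 0.0 internally, so standard scaling ahead of it is exactly
  mean-binarization of continuous features, and any positive rescaling
  ahead of the threshold is a no-op — both equivalences are asserted in the
  test suite.
* The naive Bayes family (Gaussian, Bernoulli, multinomial event models
  with Lidstone smoothing) is implemented in-package: the Bernoulli
  variant's binarize-then-model semantics is load-bearing for the method,
  and no installed package provides Bernoulli/multinomial event models
  over numeric matrices. The Gaussian variant is cross-checked against
  e1071 in the tests.
* ROC AUC is the Mann-Whitney rank statistic (ties count one half),
  checked against an exhaustive pair-counting oracle; PR AUC is step-wise
  average precision, not trapezoidal, to avoid optimistic interpolation.
* Threshold metrics (precision/recall/confusion) use 0.5 on the class-1
  score.
* Polynomial expansion is degree 2 without a bias column: `d + d(d+1)/2`
  output columns.
* RFE and select-from-model rank features with an extra-trees importance
  estimator (seeded from the pipeline seed); RFE removes a `step` fraction
  per iteration until the feature set is halved.
* The rounding convention everywhere a count is derived from a fraction is
  round-half-away-from-zero.

## Permutation feature importance

With the fitted pipeline held fixed, each feature's column is permuted
(seeded per (feature, repeat)) and the drop in balanced accuracy recorded;
the mean over repeats (100 in the full protocol) is the feature's score.
Constant features score exactly zero (a permutation of a constant is the
same data); features the model provably ignores score exactly zero as
well. Which split to permute is a config choice (`pfi_split`), defaulting
to the full profile dataset. Head ablation complements PFI at the operator
level: pre-processors are removed one at a time from the *input end* of
the pipeline (the operator nearest the data leaf first, matching the
published reading of "first pre-processors"), refitting and re-scoring
after each removal down to the bare classifier.

## Search-space arithmetic

`grid_size()` is the plain product of domain sizes: five hyperparameters
with ten values each give 100 000 grid evaluations.
`preprocessor_search_space()` multiplies a grid count by the number of
ordered arrangements of up to `p` distinct pre-processors (empty chain
included), `sum(k=0..p) p!/(p-k)!`, via the recurrence `a(p) = p a(p-1) +
1`; for `p = 10` the arrangement factor is 9 864 101, so a 100 000-point
grid grows to 986 410 100 000 combinations — about 9.86e11. (The prose
this construction comes from quotes "beyond 9.8 trillion", which matches
the leading digits but not the magnitude of the stated construction; the
package implements the defined computation and surfaces the discrepancy
here rather than matching the headline number.)

## Desk-scale protocols

The full protocol — population 1000, 1000 generations or 24 h, 10-fold CV,
50 seeds — is supported by configuration but far beyond a test suite. The
shipped experiments use deliberately scaled problem sizes, chosen once and
documented here:

* *XOR search-effectiveness benchmark*: n = 400, 10 features, population
  50, 15 generations, 50 seeds, 3-fold CV fitness, 25-tree ensembles, and
  `stop_at_perfect` on (fitness is bounded by 1, so stopping at a perfect
  score can only understate the search's result). The evolved best is
  compared against a grid-search-tuned bare logistic regression on the
  same data; the expected gain is ~0.5 against a 0.2 acceptance margin, so
  the scaled protocol leaves enormous headroom.
* *Planted-recovery check*: default cohort shape, effect size 1.0, an
  extra-trees probe pipeline, 10 PFI repeats (ranking stability needs far
  fewer repeats than coefficient estimation), 10 seeds.
* *Protocol-shape experiment*: default cohort, full seven-model roster,
  population 10, 2 generations, 2 seeds, 3-fold CV, 25-tree ensembles.

## Known limitations

* Regression targets, multi-class labels and survival outcomes are out of
  scope.
* The operator catalog's hyperparameter domains are finite lists modeled
  on the reference tool's defaults, not exhaustive ranges.
* A greedy single decision tree cannot represent the pure-XOR interaction
  regardless of depth budget (see above); claims about "tree classifiers"
  capturing interactions hold for randomized ensembles, not greedy CART.
* Per-pipeline evaluations are independent and could run concurrently with
  identical results; the shipped implementation is serial.
* No calibration analysis, decision curves, or significance tests between
  models are provided.
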