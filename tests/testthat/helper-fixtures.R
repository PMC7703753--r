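# Shared fixture builders. All randomness is locally seeded so the suite is
# deterministic end to end.

rand_table <- function(n, d, seed) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * d), n, d,
                       dimnames = list(sprintf("s%03d", 1:n),
                                       sprintf("f%d", 1:d))))
}

rand_dataset <- function(n, d, seed, p1 = 0.5) {
  set.seed(seed)
  tab <- rand_table(n, d, seed + 1)
  y <- rbinom(n, 1, p1)
  # guarantee both classes
  if (sum(y) == 0) y[1] <- 1L
  if (sum(y) == n) y[1] <- 0L
  labeled_dataset(tab, y)
}

# linearly separable two-class dataset
separable_dataset <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- cbind(rnorm(n, mean = 6 * y), rnorm(n))
  colnames(x) <- c("sig", "noise")
  labeled_dataset(feature_table(x, sample_ids = sprintf("s%03d", 1:n)), y)
}

# cheap catalog for search-loop tests: small ensembles keep fitness
# evaluation fast without touching the search logic under test
cheap_catalog <- function() full_configuration(n_estimators = 10)

bare_tree <- function(clf = "gaussian_nb", params = list()) {
  pipeline_tree(pipetree:::node_op(clf, params, pipetree:::node_data()))
}

# brute-force KNN imputation oracle: enumerates all pairwise distances over
# mutually observed features (coverage-scaled) and averages the k nearest
# donors' values
knn_oracle <- function(values, k) {
  n <- nrow(values); d <- ncol(values)
  out <- values
  for (i in 1:n) for (j in 1:d) {
    if (!is.na(values[i, j])) next
    dists <- rep(Inf, n)
    for (o in 1:n) {
      if (o == i || is.na(values[o, j])) next
      both <- which(!is.na(values[i, ]) & !is.na(values[o, ]))
      if (!length(both)) next
      dists[o] <- sqrt(sum((values[i, both] - values[o, both])^2) *
                         d / length(both))
    }
    donors <- order(dists, 1:n)[seq_len(min(k, sum(is.finite(dists))))]
    donors <- donors[is.finite(dists[donors])]
    out[i, j] <- mean(values[donors, j])
  }
  out
}

# exhaustive pair-counting ROC AUC oracle
roc_oracle <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
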