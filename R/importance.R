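#' Permutation feature importance
#'
#' Scores each feature by the mean drop in balanced accuracy when its values
#' are randomly permuted, the model held fixed: the pipeline's baseline
#' balanced accuracy is computed on the chosen data, then for each feature
#' and repeat the column is permuted (seed derived from `(seed, feature,
#' repeat)`), the *same* fitted pipeline re-scores the modified data, and
#' the decrease `baseline - permuted score` is recorded. A feature the model
#' ignores scores exactly zero in expectation; a constant feature scores
#' exactly zero always.
#'
#' @param fitted a `fitted_pipeline` from [fit_pipeline()].
#' @param data a [labeled_dataset()] with no missing values. Which split to
#'   pass (train, validation or the full dataset) is the caller's choice;
#'   the experiment driver defaults to the full dataset.
#' @param n_repeats permutations per feature (default 100).
#' @param seed integer seed.
#' @return an object of class `pfi_result`: a list with `table` (features
#'   sorted by mean decrease, with per-feature standard deviations),
#'   `decreases` (an `n_repeats` x features matrix) and `baseline_score`.
#' @export
permutation_importance <- function(fitted, data, n_repeats = 100, seed = 1) {
  stopifnot(inherits(fitted, "fitted_pipeline"),
            inherits(data, "labeled_dataset"))
  if (n_repeats <= 0) stop("n_repeats must be positive")
  x <- data$table$values
  if (anyNA(x)) stop("data must be imputed before computing importances")
  y <- data$labels
  baseline <- balanced_accuracy(y, predict(fitted, x)$class)
  d <- ncol(x)
  n <- nrow(x)
  dec <- matrix(NA_real_, n_repeats, d,
                dimnames = list(NULL, data$table$feature_names))
  for (f in seq_len(d)) {
    for (r in seq_len(n_repeats)) {
      xp <- x
      xp[, f] <- x[with_seed(derive_seed(seed, f, r),
                             sample.int(n)), f]
      dec[r, f] <- baseline - balanced_accuracy(y, predict(fitted, xp)$class)
    }
  }
  mean_dec <- colMeans(dec)
  ord <- order(-mean_dec, seq_len(d))
  structure(list(
    table = data.frame(feature = data$table$feature_names[ord],
                       mean_decrease = mean_dec[ord],
                       sd_decrease = apply(dec, 2, stats::sd)[ord],
                       row.names = NULL),
    decreases = dec,
    baseline_score = baseline,
    n_repeats = n_repeats), class = "pfi_result")
}

#' @export
print.pfi_result <- function(x, n = 10, ...) {
  cat(sprintf("<pfi_result> baseline bal_acc=%.4f, %d repeats; top features:\n",
              x$baseline_score, x$n_repeats))
  print(utils::head(x$table, n))
  invisible(x)
}

#' Planted-signal recovery fraction
#'
#' For a synthetic dataset with known informative features, the fraction of
#' the informative set recovered among the top-`k` permutation-importance
#' features: `|top_k intersect informative| / min(top_k, n_informative)`.
#'
#' @param truth a `synthetic_ground_truth` (see [generate_synthetic()]).
#' @param pfi a [permutation_importance()] result.
#' @param top_k number of top-ranked features considered.
#' @return a real in \[0, 1\].
#' @export
planted_recovery_check <- function(truth, pfi, top_k = 10) {
  stopifnot(inherits(pfi, "pfi_result"))
  top <- utils::head(pfi$table$feature, top_k)
  inf_names <- truth$informative_names
  length(intersect(top, inf_names)) / min(top_k, length(inf_names))
}
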