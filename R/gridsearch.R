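#' Number of grid-search combinations
#'
#' Product of the hyperparameter domain sizes; the empty grid counts as the
#' single default combination.
#'
#' @param param_grid named list mapping hyperparameter names to value
#'   vectors.
#' @return an integer-valued count.
#' @export
grid_size <- function(param_grid) {
  if (!length(param_grid)) return(1)
  prod(vapply(param_grid, length, 0))
}

#' Search-space size with ordered pre-processor chains
#'
#' Multiplies a grid-search combination count by the number of ordered
#' arrangements of up to `n_preprocessors` distinct pre-processors (each
#' used at most once, order significant, empty chain included):
#' \eqn{\sum_{k=0}^{p} p!/(p-k)!}, computed by the recurrence
#' \eqn{a(p) = p\,a(p-1) + 1}. This is the estimate for pre-processors with
#' no hyperparameters of their own.
#'
#' @param grid_combinations base combination count (e.g. [grid_size()]).
#' @param n_preprocessors number of available pre-processors.
#' @return a count (exact in double precision for moderate `p`).
#' @export
preprocessor_search_space <- function(grid_combinations, n_preprocessors) {
  stopifnot(n_preprocessors >= 0)
  a <- 1 # a(0): the empty chain
  for (p in seq_len(n_preprocessors)) a <- p * a + 1
  grid_combinations * a
}

# ordered preprocessor chain -> pipeline tree ending in the classifier
chain_tree <- function(classifier_name, clf_params, preprocessors) {
  node <- node_data()
  for (pre in preprocessors) {
    node <- node_op(pre$name, pre$params %||% list(), node)
  }
  pipeline_tree(node_op(classifier_name, clf_params, node))
}

#' Exhaustive grid search for one classifier
#'
#' Evaluates every Cartesian hyperparameter combination by stratified
#' k-fold cross-validated balanced accuracy on the training split, refits
#' the best combination (ties go to the first in enumeration order) on the
#' full training split, and reports metrics on both splits. A fixed
#' pre-processor chain can be prepended to every evaluated pipeline, e.g.
#' standard scaling followed by recursive feature elimination.
#'
#' @param classifier_name internal classifier name.
#' @param param_grid named list of finite value vectors; empty list = single
#'   default fit.
#' @param data training [labeled_dataset()].
#' @param n_folds CV folds.
#' @param seed integer seed.
#' @param preprocessors optional list of `list(name =, params =)` entries,
#'   applied in order before the classifier.
#' @param validation optional validation `labeled_dataset` for the report.
#' @return a list of class `grid_search_result` with `best_params`, `tree`,
#'   `record` (the winning [evaluate_cv()] fitness), `report_train`,
#'   `report_validation`, `complexity` and `n_evaluated`.
#' @export
grid_search <- function(classifier_name, param_grid, data, n_folds = 10,
                        seed = 1, preprocessors = list(), validation = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(param_grid)) stop("param_grid must be a (possibly empty) list")
  combos <- if (length(param_grid)) {
    g <- do.call(expand.grid,
                 c(param_grid, list(stringsAsFactors = FALSE,
                                    KEEP.OUT.ATTRS = FALSE)))
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  } else {
    list(list())
  }
  best <- NULL
  best_fit <- -Inf
  best_i <- NA_integer_
  for (i in seq_along(combos)) {
    tree <- chain_tree(classifier_name, combos[[i]], preprocessors)
    rec <- evaluate_cv(tree, data, n_folds, seed = seed)
    if (rec_fitness(rec) > best_fit) {
      best_fit <- rec_fitness(rec)
      best <- list(tree = tree, record = rec, params = combos[[i]])
      best_i <- i
    }
  }
  if (is.null(best)) stop("every grid combination failed to evaluate")
  fp <- fit_pipeline(best$tree, data, seed = derive_seed(seed, 5000L))
  report_for <- function(ds) {
    pr <- predict(fp, ds)
    classification_report(ds$labels, pr$class, pr$score)
  }
  structure(list(
    classifier = classifier_name,
    best_params = best$params,
    best_index = best_i,
    tree = best$tree,
    record = best$record,
    fitted = fp,
    report_train = report_for(data),
    report_validation = if (!is.null(validation)) report_for(validation),
    complexity = complexity(best$tree),
    n_evaluated = length(combos)), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> %s: CV bal_acc=%.4f over %d combination(s), complexity %d\n",
    x$classifier, x$record$mean_cv_balanced_accuracy, x$n_evaluated,
    x$complexity))
  invisible(x)
}

# baseline hyperparameter grids used by the experiment driver; modest subsets
# of the catalog domains so an exhaustive sweep stays exhaustive-but-feasible
baseline_grid <- function(classifier_name) {
  switch(classifier_name,
    logistic_regression = list(C = c(1e-3, 1e-2, 1e-1, 1, 10, 25),
                               penalty = c("l1", "l2")),
    decision_tree = list(max_depth = c(2, 4, 6, 8, 10),
                         min_samples_split = c(2, 10, 20),
                         min_samples_leaf = c(1, 10)),
    random_forest = list(max_features = c(0.1, 0.5, 1),
                         min_samples_leaf = c(1, 10)),
    bernoulli_nb = list(alpha = c(1e-2, 1e-1, 1, 10),
                        fit_prior = c(TRUE, FALSE)),
    stop("no baseline grid defined for ", classifier_name))
}
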