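# Operator catalog: the search space of the pipeline optimizer. Every
# hyperparameter domain is a finite, non-empty list, because the genetic
# search mutates by re-sampling values from these domains. The full
# configuration has exactly 11 classifiers, 14 transformers/constructors and
# 5 selectors; a reduced configuration keeps the full transformer/selector
# set but a single classifier.

operator_spec <- function(name, kind, hyperparameters = list(), arity = 1L) {
  kind <- match.arg(kind, c("transformer", "selector", "constructor",
                            "classifier", "combiner"))
  for (h in names(hyperparameters)) {
    dom <- hyperparameters[[h]]
    if (!length(dom)) stop("empty hyperparameter domain: ", name, "$", h)
  }
  structure(list(name = name, kind = kind,
                 hyperparameters = hyperparameters, arity = as.integer(arity)),
            class = "operator_spec")
}

classifier_domains <- function(n_estimators = 100) {
  c_grid <- c(1e-4, 1e-3, 1e-2, 1e-1, 0.5, 1, 5, 10, 15, 20, 25)
  list(
    logistic_regression = list(C = c_grid, penalty = c("l1", "l2")),
    decision_tree = list(max_depth = 1:10,
                         min_samples_split = c(2, 5, 10, 20),
                         min_samples_leaf = c(1, 5, 10, 20)),
    random_forest = list(n_estimators = n_estimators,
                         max_features = c(0.1, 0.25, 0.5, 0.75, 1),
                         min_samples_leaf = c(1, 5, 10, 20),
                         bootstrap = c(TRUE, FALSE)),
    extra_trees = list(n_estimators = n_estimators,
                       max_features = c(0.1, 0.25, 0.5, 0.75, 1),
                       min_samples_leaf = c(1, 5, 10, 20)),
    gradient_boosting = list(n_estimators = n_estimators,
                             learning_rate = c(0.01, 0.1, 0.5, 1),
                             max_depth = c(1, 3, 5, 7, 10),
                             subsample = c(0.5, 0.75, 1)),
    k_neighbors = list(n_neighbors = c(1, 3, 5, 7, 11, 15, 21, 31, 51)),
    linear_svc = list(C = c_grid),
    mlp = list(alpha = c(1e-4, 1e-3, 1e-2, 1e-1), hidden_units = 10),
    gaussian_nb = list(),
    bernoulli_nb = list(alpha = c(1e-3, 1e-2, 1e-1, 1, 10, 100),
                        fit_prior = c(TRUE, FALSE)),
    multinomial_nb = list(alpha = c(1e-3, 1e-2, 1e-1, 1, 10, 100),
                          fit_prior = c(TRUE, FALSE))
  )
}

transformer_domains <- function(classifier_names) {
  list(
    standard_scaler = list(),
    min_max_scaler = list(),
    max_abs_scaler = list(),
    binarizer = list(threshold = c(0, 0.1, 0.2, 0.3, 0.4, 0.5,
                                   0.6, 0.7, 0.8, 0.9, 1)),
    normalizer = list(norm = c("l2", "l1", "max")),
    polynomial_features = list(),
    pca = list(n_components = c(0.5, 0.75, 1)),
    ica = list(tol = c(1e-4, 0.05, 0.25, 0.5, 1)),
    nystroem = list(gamma = c(0.01, 0.1, 0.5, 1), n_components = 1:10),
    rbf_sampler = list(gamma = c(0.01, 0.1, 0.5, 1)),
    zero_counts = list(),
    stacking_estimator = list(estimator = classifier_names),
    one_hot_encoder = list(max_levels = 10),
    feature_agglomeration = list(linkage = c("ward.D2", "complete", "average"),
                                 n_clusters = c(2, 4, 8, 16))
  )
}

selector_domains <- function() {
  list(
    variance_threshold = list(threshold = c(1e-4, 0.001, 0.01, 0.05, 0.1, 0.2)),
    select_percentile = list(percentile = c(1, 5, 10, 20, 30, 40, 50,
                                            60, 70, 80, 90, 99)),
    select_fwe = list(alpha = c(0.001, 0.005, 0.01, 0.025, 0.05)),
    rfe = list(step = c(0.1, 0.25, 0.5, 0.75, 1)),
    select_from_model = list(threshold = c(0, 0.01, 0.05, 0.1))
  )
}

build_catalog <- function(classifier_names, mode, n_estimators = 100) {
  cd <- classifier_domains(n_estimators)
  unknown <- setdiff(classifier_names, names(cd))
  if (length(unknown)) {
    stop("unknown classifier(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(cd), collapse = ", "))
  }
  specs <- c(
    lapply(classifier_names, function(nm) {
      operator_spec(nm, "classifier", cd[[nm]])
    }),
    local({
      td <- transformer_domains(classifier_names)
      lapply(names(td), function(nm) {
        operator_spec(nm, op_kinds()[[nm]], td[[nm]])
      })
    }),
    local({
      sd <- selector_domains()
      lapply(names(sd), function(nm) operator_spec(nm, "selector", sd[[nm]]))
    })
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(specs = specs, mode = mode), class = "operator_catalog")
}

#' The full operator configuration
#'
#' Returns the complete search space: 11 classification algorithms
#' (logistic regression, decision tree, random forest, extra trees,
#' gradient tree boosting, k-nearest neighbours, linear support-vector
#' classifier, multilayer perceptron, and the Gaussian, Bernoulli and
#' multinomial naive Bayes family), 14 feature transformers/constructors and
#' 5 feature selectors, each with a finite hyperparameter domain.
#'
#' @param n_estimators tree count for the ensemble classifiers (random
#'   forest, extra trees, gradient boosting). The default, 100, mirrors the
#'   reference tool; smaller values give proportionally cheaper fitness
#'   evaluations for desk-scale experiments.
#' @return an object of class `operator_catalog`.
#' @export
full_configuration <- function(n_estimators = 100) {
  build_catalog(names(classifier_domains()), "full", n_estimators)
}

#' A reduced operator configuration
#'
#' Same transformer and selector set as [full_configuration()] but exactly
#' one classifier, as used for classifier-specific pipeline searches.
#'
#' @param classifier_name one of the full catalog's classifier names.
#' @inheritParams full_configuration
#' @return an `operator_catalog` with a single classifier spec.
#' @export
reduced_configuration <- function(classifier_name, n_estimators = 100) {
  build_catalog(classifier_name, paste0("reduced(", classifier_name, ")"),
                n_estimators)
}

catalog_classifiers <- function(catalog) {
  names(Filter(function(s) s$kind == "classifier", catalog$specs))
}

catalog_operators <- function(catalog) {
  names(Filter(function(s) s$kind %in% c("transformer", "constructor",
                                         "selector"), catalog$specs))
}

#' @export
print.operator_catalog <- function(x, ...) {
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat(sprintf(
    "<operator_catalog> mode=%s: %d classifiers, %d transformers/constructors, %d selectors\n",
    x$mode, sum(kinds == "classifier"),
    sum(kinds %in% c("transformer", "constructor")), sum(kinds == "selector")))
  invisible(x)
}

#' Write / read an operator catalog as a readable YAML config
#'
#' Serializes operator names, kinds and hyperparameter domains so that
#' custom or reduced configurations can be declared without code changes.
#'
#' @param catalog an `operator_catalog`.
#' @param path file path.
#' @return `read_catalog` returns an `operator_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  obj <- list(mode = catalog$mode,
              operators = lapply(catalog$specs, function(s) {
                list(kind = s$kind, hyperparameters = s$hyperparameters)
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- lapply(names(obj$operators), function(nm) {
    o <- obj$operators[[nm]]
    hp <- lapply(o$hyperparameters, unlist)
    operator_spec(nm, o$kind, hp)
  })
  names(specs) <- names(obj$operators)
  structure(list(specs = specs, mode = obj$mode), class = "operator_catalog")
}
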