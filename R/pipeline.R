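# Pipeline expression trees. A pipeline is a tree whose leaves are copies of
# the dataset, whose internal nodes are transformer/selector/constructor
# applications (with chosen hyperparameter values), whose optional combine
# nodes column-concatenate the outputs of two or more branches, and whose
# root is the single classifier. Complexity is the number of operator nodes
# including the classifier; combine nodes and dataset leaves do not count.

op_abbrev <- c(
  logistic_regression = "LR", decision_tree = "DT", random_forest = "RF",
  extra_trees = "ET", gradient_boosting = "GB", k_neighbors = "KNN",
  linear_svc = "LSVC", mlp = "MLP", gaussian_nb = "GNB",
  bernoulli_nb = "BNB", multinomial_nb = "MNB",
  standard_scaler = "SS", min_max_scaler = "MMS", max_abs_scaler = "MAS",
  binarizer = "BIN", normalizer = "NORM", polynomial_features = "POLY",
  pca = "PCA", ica = "ICA", nystroem = "NYS", rbf_sampler = "RBFS",
  zero_counts = "ZC", stacking_estimator = "SE", one_hot_encoder = "OH",
  feature_agglomeration = "FA", variance_threshold = "VT",
  select_percentile = "SP", select_fwe = "FWE", rfe = "RFE",
  select_from_model = "SFM"
)

abbrev_op <- stats::setNames(names(op_abbrev), op_abbrev)

node_data <- function() list(kind = "data")
node_combine <- function(children) list(kind = "combine", children = children)
node_op <- function(name, params, child) {
  kind <- if (name %in% names(classifier_domains())) "classifier" else "operator"
  list(kind = kind, name = name, params = params, children = list(child))
}

#' Construct a pipeline tree
#'
#' @param root the root classifier node (use [parse_pipeline()] or
#'   [random_pipeline()] to build trees).
#' @return an object of class `pipeline_tree`.
#' @export
pipeline_tree <- function(root) {
  tree <- structure(list(root = root), class = "pipeline_tree")
  validate_pipeline(tree)
  tree
}

validate_pipeline <- function(tree, max_operators = Inf) {
  root <- tree$root
  if (!identical(root$kind, "classifier")) {
    stop("pipeline root must be the classifier")
  }
  n_clf <- 0L
  walk <- function(node) {
    if (node$kind == "classifier") n_clf <<- n_clf + 1L
    if (node$kind == "combine" && length(node$children) < 2) {
      stop("combine nodes need at least 2 children")
    }
    if (node$kind %in% c("operator", "classifier") &&
        length(node$children) != 1) {
      stop("operator nodes take exactly one input")
    }
    for (ch in node$children %||% list()) walk(ch)
  }
  walk(root)
  if (n_clf != 1L) stop("pipeline must contain exactly one classifier")
  k <- complexity(tree)
  if (k < 1 || k > max_operators) {
    stop("pipeline complexity ", k, " outside [1, ", max_operators, "]")
  }
  invisible(TRUE)
}

#' Pipeline complexity
#'
#' The number of operator nodes in the tree, classifier included: a bare
#' classifier has complexity 1; combine nodes and dataset leaves are not
#' counted.
#'
#' @param tree a [pipeline_tree()].
#' @return a positive integer.
#' @export
complexity <- function(tree) {
  count <- function(node) {
    own <- as.integer(node$kind %in% c("operator", "classifier"))
    own + sum(vapply(node$children %||% list(), count, integer(1)))
  }
  count(tree$root)
}

# ---- serialization ---------------------------------------------------------

fmt_value <- function(v) {
  if (is.logical(v)) return(as.character(v))
  if (is.numeric(v)) return(as.character(v))
  as.character(v)
}

fmt_params <- function(name, params) {
  if (identical(name, "stacking_estimator")) {
    est <- params$estimator
    inner <- params$est_params %||% list()
    parts <- c(paste0("est=", op_abbrev[[est]]),
               vapply(names(inner), function(k) {
                 paste0(k, "=", fmt_value(inner[[k]]))
               }, character(1)))
    return(paste(parts, collapse = ","))
  }
  if (!length(params)) return("")
  paste(vapply(names(params), function(k) {
    paste0(k, "=", fmt_value(params[[k]]))
  }, character(1)), collapse = ",")
}

serialize_node <- function(node) {
  switch(node$kind,
    data = "DATA",
    combine = paste0("COMB[", paste(vapply(node$children, serialize_node,
                                           character(1)), collapse = "; "),
                     "]"),
    paste0(op_abbrev[[node$name]], "(", fmt_params(node$name, node$params),
           ")<-", serialize_node(node$children[[1]]))
  )
}

#' Serialize a pipeline tree to text
#'
#' Writes the tree in a stable s-expression-like form, e.g.
#' `BNB(alpha=1,fit_prior=TRUE)<-SS()<-SE(est=LR,C=1,penalty=l2)<-DATA`,
#' that [parse_pipeline()] inverts exactly.
#'
#' @param tree a [pipeline_tree()].
#' @return a character scalar.
#' @export
serialize_pipeline <- function(tree) serialize_node(tree$root)

#' @export
format.pipeline_tree <- function(x, ...) serialize_pipeline(x)

#' @export
print.pipeline_tree <- function(x, ...) {
  cat("<pipeline_tree> ", serialize_pipeline(x), "\n", sep = "")
  invisible(x)
}

parse_value <- function(s) {
  if (s %in% c("TRUE", "FALSE")) return(as.logical(s))
  if (grepl("^-?[0-9.]+(e-?[0-9]+)?$", s)) return(as.numeric(s))
  s
}

# split s on `sep` at bracket depth 0
split_top <- function(s, sep) {
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  n <- nchar(sep)
  pieces <- character(0)
  start <- 1L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (depth == 0L && i + n - 1L <= length(chars) &&
        substr(s, i, i + n - 1L) == sep) {
      pieces <- c(pieces, substr(s, start, i - 1L))
      i <- i + n
      start <- i
      next
    }
    i <- i + 1L
  }
  c(pieces, substr(s, start, nchar(s)))
}

parse_node <- function(s) {
  s <- trimws(s)
  if (identical(s, "DATA")) return(node_data())
  if (startsWith(s, "COMB[")) {
    inner <- substr(s, 6, nchar(s) - 1)
    return(node_combine(lapply(split_top(inner, "; "), parse_node)))
  }
  m <- regexpr("^([A-Z]+)\\(", s)
  if (m == -1) stop("unparseable pipeline node: ", s)
  abbr <- sub("^([A-Z]+)\\(.*$", "\\1", s)
  if (!abbr %in% names(abbrev_op)) stop("unknown operator code: ", abbr)
  rest <- substr(s, nchar(abbr) + 1, nchar(s))
  # rest = "(args)<-child"
  head_child <- split_top(rest, "<-")
  args_str <- head_child[1]
  args_str <- substr(args_str, 2, nchar(args_str) - 1)
  params <- list()
  if (nzchar(args_str)) {
    for (kv in split_top(args_str, ",")) {
      eq <- regexpr("=", kv, fixed = TRUE)
      params[[substr(kv, 1, eq - 1)]] <- parse_value(substr(kv, eq + 1,
                                                            nchar(kv)))
    }
  }
  name <- abbrev_op[[abbr]]
  if (identical(name, "stacking_estimator")) {
    est <- abbrev_op[[params$est]]
    inner <- params[setdiff(names(params), "est")]
    params <- list(estimator = est, est_params = inner)
  }
  if (length(head_child) < 2) stop("operator node without input: ", s)
  child <- parse_node(paste(head_child[-1], collapse = "<-"))
  node_op(name, params, child)
}

#' Parse a serialized pipeline
#'
#' @param text output of [serialize_pipeline()].
#' @return a [pipeline_tree()].
#' @export
parse_pipeline <- function(text) pipeline_tree(parse_node(text))

# ---- random generation -----------------------------------------------------

sample_spec_params <- function(spec, catalog) {
  params <- lapply(spec$hyperparameters, draw_one)
  if (identical(spec$name, "stacking_estimator")) {
    est <- params$estimator
    est_spec <- catalog$specs[[est]]
    params <- list(estimator = est,
                   est_params = lapply(est_spec$hyperparameters, draw_one))
  }
  params
}

#' Generate a random pipeline
#'
#' Draws a structurally valid tree: a classifier at the root over a chain of
#' randomly chosen operators with hyperparameters sampled uniformly from
#' their domains; the operator count beyond the classifier is geometrically
#' distributed (small trees are likelier) and capped at `max_operators - 1`.
#' Occasionally two branches are grown and joined by a combine node.
#'
#' @param catalog an `operator_catalog`.
#' @param max_operators complexity cap (classifier included).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return a [pipeline_tree()].
#' @export
random_pipeline <- function(catalog, max_operators = 10, seed = NULL) {
  gen <- function() {
    n_extra_max <- max_operators - 1L
    n_extra <- if (n_extra_max > 0) {
      w <- 0.5^(0:n_extra_max)
      sample.int(n_extra_max + 1L, 1, prob = w / sum(w)) - 1L
    } else 0L
    ops <- catalog_operators(catalog)
    grow_chain <- function(k, base) {
      node <- base
      for (i in seq_len(k)) {
        nm <- draw_one(ops)
        node <- node_op(nm, sample_spec_params(catalog$specs[[nm]], catalog),
                        node)
      }
      node
    }
    body <- if (n_extra >= 2 && stats::runif(1) < 0.2) {
      k1 <- sample.int(n_extra - 1L, 1)
      node_combine(list(grow_chain(k1, node_data()),
                        grow_chain(n_extra - k1, node_data())))
    } else {
      grow_chain(n_extra, node_data())
    }
    clf <- draw_one(catalog_classifiers(catalog))
    pipeline_tree(node_op(clf, sample_spec_params(catalog$specs[[clf]],
                                                  catalog), body))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# ---- fitting and prediction ------------------------------------------------

#' Fit a pipeline on a labeled dataset
#'
#' Operators are fit leaf-to-root, each on the (already transformed)
#' training data only; combine nodes concatenate their children's columns;
#' the root classifier is fit last. The returned object replays the learned
#' transformations on new data without any refitting.
#'
#' @param tree a [pipeline_tree()].
#' @param train a [labeled_dataset()] with no missing values.
#' @param seed integer seed for stochastic operators and classifiers.
#' @return an object of class `fitted_pipeline`.
#' @export
fit_pipeline <- function(tree, train, seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"))
  x <- train$table$values
  if (anyNA(x)) stop("training data must be imputed before fitting")
  y <- train$labels
  counter <- 0L
  fit_node <- function(node) {
    counter <<- counter + 1L
    my_seed <- derive_seed(seed, counter)
    switch(node$kind,
      data = list(node = node, out = x),
      combine = {
        kids <- lapply(node$children, fit_node)
        list(node = node, kids = kids,
             out = do.call(cbind, lapply(kids, `[[`, "out")))
      },
      operator = {
        kid <- fit_node(node$children[[1]])
        f <- op_fit(node$name, node$params, kid$out, y, seed = my_seed)
        out <- op_apply(f, kid$out)
        # resource guard: stacked constructors (e.g. repeated polynomial
        # expansion) can blow the width up combinatorially; such pipelines
        # are treated as evaluation failures, like any other operator error
        if (ncol(out) > 1024) stop("feature explosion: ", ncol(out),
                                   " columns")
        list(node = node, kid = kid, fitted = f, out = out)
      },
      classifier = {
        kid <- fit_node(node$children[[1]])
        list(node = node, kid = kid,
             fitted = clf_fit(node$name, kid$out, y, node$params,
                              seed = my_seed))
      })
  }
  fitted <- fit_node(tree$root)
  structure(list(tree = tree, fitted = fitted, seed = seed),
            class = "fitted_pipeline")
}

#' Predict from a fitted pipeline
#'
#' @param object a `fitted_pipeline`.
#' @param newdata a `feature_table`, `labeled_dataset` or numeric matrix
#'   sharing the training feature set.
#' @param ... unused.
#' @return a list with `class` (0/1 predictions) and `score` (real-valued
#'   class-1 scores usable for ROC/PR curves).
#' @export
predict.fitted_pipeline <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$table
  xnew <- if (inherits(newdata, "feature_table")) newdata$values else
    as.matrix(newdata)
  apply_node <- function(fn, xx) {
    switch(fn$node$kind,
      data = xx,
      combine = do.call(cbind, lapply(fn$kids, apply_node, xx)),
      operator = op_apply(fn$fitted, apply_node(fn$kid, xx)),
      classifier = clf_predict(fn$fitted, apply_node(fn$kid, xx)))
  }
  apply_node(object$fitted, xnew)
}

#' Fit a pipeline and predict on a test table
#'
#' Convenience wrapper around [fit_pipeline()] and
#' [predict.fitted_pipeline()].
#'
#' @inheritParams fit_pipeline
#' @param test a `feature_table` (or matrix) sharing `train`'s feature set.
#' @return a list with `class` and `score` for `test`.
#' @export
fit_predict <- function(tree, train, test, seed = 1) {
  predict(fit_pipeline(tree, train, seed = seed), test)
}

# ---- cross-validated fitness -----------------------------------------------

fitness_record <- function(per_fold, comp, valid = TRUE) {
  structure(list(
    mean_cv_balanced_accuracy = if (valid) mean(per_fold) else -Inf,
    per_fold_scores = per_fold,
    complexity = comp,
    valid = valid), class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> mean CV bal_acc=%s complexity=%d%s\n",
              format(x$mean_cv_balanced_accuracy, digits = 4), x$complexity,
              if (x$valid) "" else " (invalid)"))
  invisible(x)
}

# stratified fold assignment computed on sorted sample ids so that the
# folds (hence the fitness) are invariant to row permutations of the input
cv_folds <- function(labels, sample_ids, n_folds, seed) {
  ord <- order(sample_ids)
  fold <- integer(length(labels))
  for (cl in 0:1) {
    pool <- ord[labels[ord] == cl]
    shuf <- with_seed(derive_seed(seed, cl, n_folds),
                      pool[sample.int(length(pool))])
    fold[shuf] <- rep_len(seq_len(n_folds), length(shuf))
  }
  fold
}

#' Cross-validated pipeline fitness
#'
#' Evaluates a pipeline by stratified k-fold cross-validation (default
#' 10-fold) with per-fold balanced accuracy. Folds are deterministic in the
#' seed and invariant to row order. A failure in any fold (empty feature
#' set, non-convergence, singular transform) marks the record invalid with
#' sentinel fitness `-Inf` rather than raising, so that a search can keep
#' selecting over populations containing failures.
#'
#' @param tree a [pipeline_tree()].
#' @param data a [labeled_dataset()] with no missing values; each class must
#'   have at least `n_folds` samples.
#' @param n_folds number of folds.
#' @param seed integer seed controlling fold assignment and stochastic
#'   operators.
#' @return a `fitness_record`.
#' @export
evaluate_cv <- function(tree, data, n_folds = 10, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  y <- data$labels
  if (min(sum(y == 0), sum(y == 1)) < n_folds) {
    stop("a class has fewer than n_folds samples; use a smaller n_folds")
  }
  comp <- complexity(tree)
  fold <- cv_folds(y, data$table$sample_ids, n_folds, seed)
  per_fold <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    te <- which(fold == k)
    tr <- which(fold != k)
    res <- tryCatch({
      pred <- fit_predict(tree, labeled_dataset(ft_rows(data$table, tr),
                                                y[tr], data$profile_id),
                          data$table$values[te, , drop = FALSE],
                          seed = derive_seed(seed, k))
      balanced_accuracy(y[te], pred$class)
    }, error = function(e) NA_real_)
    if (is.na(res)) return(fitness_record(rep(NA_real_, n_folds), comp,
                                          valid = FALSE))
    per_fold[k] <- res
  }
  fitness_record(per_fold, comp)
}
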