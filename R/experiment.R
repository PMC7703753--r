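# End-to-end experiment driver: for each phenotypic profile, impute, split
# 75/25, run a roster of models (GP pipeline searches and grid-search
# baselines), report training/validation metrics per model, then run
# head-ablation and permutation importance for the best model. Reports are
# written as plain TSV/JSON so every number can be recomputed from the
# persisted seeds and config.

#' Experiment configuration
#'
#' @param roster model identifiers: any of `gp_full`, `gp_lr`,
#'   `gp_dt`, `gp_rf` (GP searches with the full or reduced catalog) and
#'   `gs_lr`, `gs_dt`, `gs_rf` (grid-search-tuned bare classifiers);
#'   `gs_composed` entries take the form
#'   `list(classifier =, preprocessors = list(...))` via `composed`.
#' @param validation_fraction hold-out fraction (default 0.25).
#' @param knn_k imputation neighbourhood size.
#' @param gp a [gp_config()] used by every GP roster entry.
#' @param n_seeds GP restarts per configuration (representative-model
#'   protocol).
#' @param n_folds CV folds for the grid-search baselines.
#' @param pfi_repeats,pfi_split permutation-importance protocol: repeats and
#'   which split to permute (`"all"`, `"validation"` or `"train"`).
#' @param n_estimators ensemble size used in the catalogs (see
#'   [full_configuration()]).
#' @param seed master seed.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(roster = c("gp_full", "gp_lr", "gp_dt",
                                         "gp_rf", "gs_lr", "gs_dt",
                                         "gs_rf"),
                              validation_fraction = 0.25, knn_k = 5,
                              gp = gp_config(), n_seeds = 50, n_folds = 10,
                              pfi_repeats = 100,
                              pfi_split = c("all", "validation", "train"),
                              n_estimators = 100, seed = 42) {
  if (!length(roster)) stop("roster must be non-empty")
  known <- c("gp_full", "gp_lr", "gp_dt", "gp_rf",
             "gs_lr", "gs_dt", "gs_rf")
  bad <- setdiff(roster, known)
  if (length(bad)) stop("unknown roster entries: ", paste(bad, collapse = ", "))
  structure(list(roster = roster,
                 validation_fraction = validation_fraction, knn_k = knn_k,
                 gp = gp, n_seeds = n_seeds, n_folds = n_folds,
                 pfi_repeats = pfi_repeats,
                 pfi_split = match.arg(pfi_split),
                 n_estimators = n_estimators, seed = seed),
            class = "experiment_config")
}

roster_catalog <- function(entry, n_estimators = 100) {
  switch(entry,
    gp_full = full_configuration(n_estimators),
    gp_lr = reduced_configuration("logistic_regression", n_estimators),
    gp_dt = reduced_configuration("decision_tree", n_estimators),
    gp_rf = reduced_configuration("random_forest", n_estimators),
    NULL)
}

roster_gs_classifier <- function(entry) {
  switch(entry, gs_lr = "logistic_regression", gs_dt = "decision_tree",
         gs_rf = "random_forest", NULL)
}

run_roster_entry <- function(entry, split, config) {
  train <- split$train
  validation <- split$validation
  cat_or_null <- roster_catalog(entry, config$n_estimators)
  if (!is.null(cat_or_null)) {
    res <- representative_model(train, cat_or_null, config$gp,
                                n_seeds = config$n_seeds)
    tree <- res$best$tree
    fp <- fit_pipeline(tree, train,
                       seed = derive_seed(config$seed, res$seed, 77L))
    rep_for <- function(ds) {
      pr <- predict(fp, ds)
      classification_report(ds$labels, pr$class, pr$score)
    }
    list(model = entry, tree = tree, fitted = fp,
         cv_record = res$best$record, search = res,
         report_validation = rep_for(validation),
         report_train = rep_for(train),
         complexity = complexity(tree))
  } else {
    clf <- roster_gs_classifier(entry)
    gs <- grid_search(clf, baseline_grid(clf), train,
                      n_folds = config$n_folds,
                      seed = derive_seed(config$seed, nchar(entry), 88L),
                      validation = validation)
    list(model = entry, tree = gs$tree, fitted = gs$fitted,
         cv_record = gs$record, search = gs,
         report_validation = gs$report_validation,
         report_train = gs$report_train,
         complexity = gs$complexity)
  }
}

model_table <- function(results) {
  tab <- do.call(rbind, lapply(results, function(r) {
    v <- r$report_validation
    t <- r$report_train
    data.frame(model = r$model,
               pipeline = serialize_pipeline(r$tree),
               bal_acc_V = v$balanced_accuracy, bal_acc_T = t$balanced_accuracy,
               precision_V = v$precision, precision_T = t$precision,
               recall_V = v$recall, recall_T = t$recall,
               roc_auc_V = v$roc_auc, roc_auc_T = t$roc_auc,
               pr_auc_V = v$pr_auc, pr_auc_T = t$pr_auc,
               complexity = r$complexity)
  }))
  # best model per profile: highest validation balanced accuracy, ties to
  # the less complex pipeline
  best <- order(-tab$bal_acc_V, tab$complexity)[1]
  tab$best <- seq_len(nrow(tab)) == best
  tab
}

#' Run a full comparison experiment
#'
#' For each profile dataset: impute missing values, split 75/25 (stratified),
#' run every roster model on the training split, assemble a model-comparison
#' table on both splits with the best model marked (highest validation
#' balanced accuracy), then run head-ablation and permutation feature
#' importance for the best model.
#'
#' @param profiles named list of [labeled_dataset()]s (e.g.
#'   `list(P1 =, P2 =)`), possibly with missing values.
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for the report bundle; must not
#'   already contain reports unless `force`.
#' @param force overwrite an existing non-empty output directory.
#' @return a list of class `experiment_bundle`, one entry per profile, each
#'   with `models` (the comparison data frame), `results`, `ablation`,
#'   `pfi`, `split` and `seed`.
#' @export
run_experiment <- function(profiles, config = experiment_config(),
                           out_dir = NULL, force = FALSE) {
  stopifnot(is.list(profiles), length(profiles) > 0)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("profiles must be a named list")
  }
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
      stop("output directory not empty (use force = TRUE): ", out_dir)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  bundle <- list()
  log_lines <- c(sprintf("experiment seed=%d roster=%s", config$seed,
                         paste(config$roster, collapse = ",")))
  for (pname in names(profiles)) {
    ds <- profiles[[pname]]
    stopifnot(inherits(ds, "labeled_dataset"))
    t0 <- Sys.time()
    if (anyNA(ds$table$values)) {
      ds <- labeled_dataset(knn_impute(ds$table, k = config$knn_k),
                            ds$labels, ds$profile_id)
    }
    split <- stratified_split(ds, config$validation_fraction,
                              seed = derive_seed(config$seed, nchar(pname)))
    results <- lapply(config$roster, function(entry) {
      te <- Sys.time()
      r <- run_roster_entry(entry, split, config)
      log_lines <<- c(log_lines,
                      sprintf("[%s] %s: cv=%.4f complexity=%d (%.1fs)",
                              pname, entry,
                              rec_fitness(r$cv_record), r$complexity,
                              as.numeric(difftime(Sys.time(), te,
                                                  units = "secs"))))
      r
    })
    models <- model_table(results)
    best_res <- results[[which(models$best)]]
    ablation <- head_ablation(best_res$tree, split$train, split$validation,
                              seed = derive_seed(config$seed, 11L))
    pfi_data <- switch(config$pfi_split, all = ds,
                       validation = split$validation, train = split$train)
    pfi <- permutation_importance(best_res$fitted, pfi_data,
                                  n_repeats = config$pfi_repeats,
                                  seed = derive_seed(config$seed, 13L))
    bundle[[pname]] <- list(models = models, results = results,
                            ablation = ablation, pfi = pfi, split = split,
                            seed = config$seed)
    log_lines <- c(log_lines,
                   sprintf("[%s] done in %.1fs; best=%s", pname,
                           as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")),
                           models$model[models$best]))
  }
  out <- structure(list(profiles = bundle, config = config,
                        log = log_lines), class = "experiment_bundle")
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an experiment bundle to disk
#'
#' Emits, per profile: a model-comparison TSV (one row per roster model,
#' validation and training metrics, complexity, best-model flag), an
#' ablation TSV, a permutation-importance TSV (feature, mean and sd of the
#' balanced-accuracy decrease) and the best model's normalized confusion
#' matrices as JSON, plus a run log and the seeds/config.
#'
#' @param bundle an `experiment_bundle`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (pname in names(bundle$profiles)) {
    b <- bundle$profiles[[pname]]
    write_tsv(b$models, file.path(out_dir, paste0("models_", pname, ".tsv")))
    write_tsv(b$ablation$table,
              file.path(out_dir, paste0("ablation_", pname, ".tsv")))
    write_tsv(b$pfi$table, file.path(out_dir, paste0("pfi_", pname, ".tsv")))
    best <- b$results[[which(b$models$best)]]
    jsonlite::write_json(
      list(model = best$model,
           confusion_validation = best$report_validation$confusion_normalized,
           confusion_train = best$report_train$confusion_normalized),
      file.path(out_dir, paste0("confusion_", pname, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  cfg <- bundle$config
  cfg$gp <- unclass(cfg$gp)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Re-run an experiment and check bit-stability
#'
#' Re-executes [run_experiment()] with the same profiles and config and
#' compares the regenerated model tables against a bundle's, returning TRUE
#' when every number matches.
#'
#' @param bundle an `experiment_bundle`.
#' @param profiles the same profile datasets the bundle was built from.
#' @return logical.
#' @export
verify_experiment <- function(bundle, profiles) {
  redo <- run_experiment(profiles, bundle$config)
  isTRUE(all.equal(lapply(bundle$profiles, `[[`, "models"),
                   lapply(redo$profiles, `[[`, "models"),
                   tolerance = 0))
}

#' @export
print.experiment_bundle <- function(x, ...) {
  for (pname in names(x$profiles)) {
    cat("== profile ", pname, " ==\n", sep = "")
    print(x$profiles[[pname]]$models[, c("model", "bal_acc_V", "bal_acc_T",
                                         "complexity", "best")],
          row.names = FALSE)
  }
  invisible(x)
}
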