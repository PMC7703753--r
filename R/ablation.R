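#' Head-ablation sensitivity analysis
#'
#' Consecutively removes pre-processing operators from the *input end* of a
#' pipeline (the operator nearest the dataset leaf first), refitting the
#' reduced pipeline on the training split after each removal and reporting
#' metrics on both splits, down to the bare classifier. Tracks how much of
#' the pipeline's performance each pre-processor carries.
#'
#' @param tree a [pipeline_tree()] of complexity `k`.
#' @param train,validation [labeled_dataset()]s with no missing values.
#' @param seed integer seed.
#' @return an object of class `ablation_table`: a list with `table` (one
#'   row per `n_removed = 0 .. k-1`, with complexity and validation/training
#'   metrics), `reports` (the full [classification_report()] pairs) and
#'   `source` (the serialized input pipeline).
#' @export
head_ablation <- function(tree, train, validation, seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(validation, "labeled_dataset"))
  k <- complexity(tree)
  trees <- vector("list", k)
  trees[[1]] <- tree
  cur <- tree
  for (i in seq_len(k - 1)) {
    cur <- remove_input_operator(cur)
    trees[[i + 1]] <- cur
  }
  reports <- lapply(seq_along(trees), function(i) {
    fp <- fit_pipeline(trees[[i]], train, seed = derive_seed(seed, i))
    rep_for <- function(ds) {
      pr <- predict(fp, ds)
      classification_report(ds$labels, pr$class, pr$score)
    }
    list(validation = rep_for(validation), training = rep_for(train),
         tree = trees[[i]])
  })
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    v <- reports[[i]]$validation
    t <- reports[[i]]$training
    data.frame(n_removed = i - 1L, complexity = complexity(trees[[i]]),
               pipeline = serialize_pipeline(trees[[i]]),
               bal_acc_V = v$balanced_accuracy, bal_acc_T = t$balanced_accuracy,
               precision_V = v$precision, precision_T = t$precision,
               recall_V = v$recall, recall_T = t$recall,
               roc_auc_V = v$roc_auc, roc_auc_T = t$roc_auc,
               pr_auc_V = v$pr_auc, pr_auc_T = t$pr_auc)
  }))
  structure(list(table = tab, reports = reports,
                 source = serialize_pipeline(tree)),
            class = "ablation_table")
}

# drop the operator node deepest in the tree (ties: the first found in
# leaf-to-root serialization order), splicing its child into its place
remove_input_operator <- function(tree) {
  paths <- subtree_paths(tree$root)
  op_paths <- Filter(function(p) {
    get_subtree(tree$root, p)$kind == "operator"
  }, paths)
  if (!length(op_paths)) stop("no pre-processing operators left to remove")
  depth <- vapply(op_paths, length, 0L)
  at <- op_paths[[which.max(depth)]]
  victim <- get_subtree(tree$root, at)
  pipeline_tree(set_subtree(tree$root, at, victim$children[[1]]))
}

#' @export
print.ablation_table <- function(x, ...) {
  cat("<ablation_table> source: ", x$source, "\n", sep = "")
  print(x$table[, c("n_removed", "complexity", "bal_acc_V", "bal_acc_T",
                    "roc_auc_V", "roc_auc_T")], row.names = FALSE)
  invisible(x)
}
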