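#' Construct a feature table
#'
#' A feature table is the package's tabular container: a numeric matrix of
#' samples x features together with a per-feature kind tag. Binary features
#' take values in \{0, 1\} (missing allowed); categorical features are stored
#' as integer level codes with the level labels kept as an attribute.
#'
#' @param values numeric matrix (samples x features); `NA` marks missing.
#' @param feature_names unique feature identifiers (defaults to colnames).
#' @param feature_kinds character vector, one of `"continuous"`, `"binary"`,
#'   `"categorical"` per feature.
#' @param sample_ids unique sample identifiers (defaults to rownames).
#' @param levels named list mapping categorical feature names to their
#'   original level labels.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, feature_names = colnames(values),
                          feature_kinds = NULL, sample_ids = rownames(values),
                          levels = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  feature_names <- as.character(feature_names)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must equal column count")
  }
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length must equal row count")
  }
  if (is.null(feature_kinds)) {
    feature_kinds <- apply(values, 2, infer_kind)
  }
  feature_kinds <- match.arg(as.character(feature_kinds),
                             c("continuous", "binary", "categorical"),
                             several.ok = TRUE)
  if (length(feature_kinds) != ncol(values)) {
    stop("feature_kinds length must equal column count")
  }
  bad_bin <- which(feature_kinds == "binary" &
                     apply(values, 2, function(v) {
                       any(!is.na(v) & !(v %in% c(0, 1)))
                     }))
  if (length(bad_bin)) {
    stop("binary features must take values in {0, 1}: ",
         paste(feature_names[bad_bin], collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, feature_names = feature_names,
         feature_kinds = stats::setNames(feature_kinds, feature_names),
         sample_ids = sample_ids, levels = levels),
    class = "feature_table"
  )
}

# kind inference rule: <=2 distinct non-missing numeric values -> binary
# (after 0/1 check by caller); else continuous. Non-numeric handling happens
# at load time (label-encoded to integer codes, kind = categorical).
infer_kind <- function(v) {
  u <- unique(v[!is.na(v)])
  if (length(u) <= 2 && all(u %in% c(0, 1))) "binary" else "continuous"
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$feature_kinds),
                            names(table(x$feature_kinds))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# column subset, preserving metadata
ft_select <- function(table, idx) {
  feature_table(table$values[, idx, drop = FALSE],
                feature_names = table$feature_names[idx],
                feature_kinds = table$feature_kinds[idx],
                sample_ids = table$sample_ids,
                levels = table$levels[intersect(names(table$levels),
                                                table$feature_names[idx])])
}

# row subset
ft_rows <- function(table, idx) {
  feature_table(table$values[idx, , drop = FALSE],
                feature_names = table$feature_names,
                feature_kinds = table$feature_kinds,
                sample_ids = table$sample_ids[idx],
                levels = table$levels)
}

#' Construct a labeled dataset
#'
#' Couples a [feature_table()] with a binary label vector and a profile tag.
#' Profiles name the two binarizations of a three-level disease severity:
#' `"P1"` (no disease vs any disease) and `"P2"` (obstructive vs rest).
#'
#' @param table a `feature_table`.
#' @param labels integer/numeric vector of 0/1 class labels, one per sample.
#' @param profile_id one of `"P1"`, `"P2"`, `"other"`.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(table, labels, profile_id = "other") {
  stopifnot(inherits(table, "feature_table"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(table$values)) {
    stop("labels length must equal sample count")
  }
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 with no missing values")
  }
  structure(list(table = table, labels = labels,
                 profile_id = match.arg(profile_id, c("P1", "P2", "other"))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> profile=%s, n=%d (class 1: %d), d=%d\n",
              x$profile_id, length(x$labels), sum(x$labels),
              ncol(x$table$values)))
  invisible(x)
}

#' Load a labeled feature table from CSV/TSV
#'
#' Reads a delimited file (first row header; delimiter inferred from the file
#' extension, `.tsv` for tab else comma), takes one column as sample id and
#' one as the binary label, infers per-feature kinds and label-encodes
#' non-numeric (categorical) columns to integer codes. Empty cells are
#' missing. The label mapping (level -> 0/1) is chosen by sort order of the
#' two observed label values and recorded in the returned object's
#' `label_mapping` attribute; samples with a missing label are dropped with a
#' message.
#'
#' @param path file path.
#' @param label_column name of the label column.
#' @param id_column name of the sample-id column; default the first column.
#' @param kind_overrides named character vector forcing feature kinds, e.g.
#'   `c(age = "continuous")`.
#' @param profile_id profile tag for the returned dataset.
#' @return a [labeled_dataset()] with attribute `label_mapping`.
#' @export
load_feature_table <- function(path, label_column, id_column = NULL,
                               kind_overrides = NULL, profile_id = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!label_column %in% names(df)) {
    stop("missing label column: ", label_column)
  }
  if (!id_column %in% names(df)) stop("missing id column: ", id_column)
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", id_column)

  lab_raw <- df[[label_column]]
  keep <- !is.na(lab_raw)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped for missing label")
    df <- df[keep, , drop = FALSE]
    ids <- ids[keep]
    lab_raw <- lab_raw[keep]
  }
  lev <- sort(unique(as.character(lab_raw)))
  if (length(lev) != 2) {
    stop("label not binary: found ", length(lev), " distinct values")
  }
  labels <- as.integer(as.character(lab_raw) == lev[2])

  feat_cols <- setdiff(names(df), c(id_column, label_column))
  if (!length(feat_cols)) stop("no feature columns")
  levels <- list()
  kinds <- character(length(feat_cols))
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(ids, feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- df[[feat_cols[j]]]
    if (is.numeric(v)) {
      # <=2 distinct non-missing values in {0,1} -> binary; two-valued
      # columns on another scale stay continuous (binary features are 0/1
      # by construction in this container)
      vals[, j] <- v
      kinds[j] <- infer_kind(v)
    } else {
      # categorical: label-encode to integer codes 0..(L-1), keep levels
      f <- factor(as.character(v))
      levels[[feat_cols[j]]] <- levels(f)
      vals[, j] <- as.numeric(f) - 1
      kinds[j] <- "categorical"
    }
  }
  if (!is.null(kind_overrides)) {
    for (nm in names(kind_overrides)) {
      if (!nm %in% feat_cols) stop("kind override for unknown feature: ", nm)
      kinds[match(nm, feat_cols)] <- match.arg(kind_overrides[[nm]],
                                               c("continuous", "binary",
                                                 "categorical"))
    }
  }
  tab <- feature_table(vals, feature_names = feat_cols, feature_kinds = kinds,
                       sample_ids = ids, levels = levels)
  ds <- labeled_dataset(tab, labels, profile_id)
  attr(ds, "label_mapping") <- stats::setNames(c(0L, 1L), lev)
  ds
}

#' K-nearest-neighbour imputation
#'
#' Replaces every missing entry by the mean of that feature over the `k`
#' nearest samples among those observing it. Nearness is Euclidean distance
#' computed over the features observed in *both* samples, scaled by the
#' fraction of usable features (so samples comparable on few features are not
#' spuriously close). Observed entries are never changed.
#'
#' @param table a [feature_table()].
#' @param k positive integer neighbourhood size (default 5), `k <` sample
#'   count.
#' @return a `feature_table` with no missing entries.
#' @export
knn_impute <- function(table, k = 5) {
  stopifnot(inherits(table, "feature_table"))
  if (length(k) != 1 || is.na(k) || k <= 0) stop("k must be a positive integer")
  x <- table$values
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the sample count")
  miss <- is.na(x)
  if (!any(miss)) return(table)
  if (any(rowSums(!miss) == 0)) {
    stop("sample(s) with all features missing cannot be imputed: ",
         paste(table$sample_ids[rowSums(!miss) == 0], collapse = ", "))
  }
  obs <- !miss
  # pairwise distances over mutually observed features, scaled by coverage:
  # d_ij = sqrt( sum_{f obs in both} (x_if - x_jf)^2 * d / n_usable )
  d <- ncol(x)
  x0 <- x
  x0[miss] <- 0
  sq <- x0^2
  cross <- tcrossprod(x0)                   # sum x_if x_jf over mutual support
  s_i <- sq %*% t(obs)                      # sum_{f obs both} x_if^2
  usable <- tcrossprod(obs * 1)             # count of mutually observed
  dist2 <- s_i + t(s_i) - 2 * cross
  dist2[dist2 < 0] <- 0
  scaled <- ifelse(usable > 0, dist2 * d / usable, Inf)
  diag(scaled) <- Inf

  out <- x
  for (i in which(rowSums(miss) > 0)) {
    for (j in which(miss[i, ])) {
      donors <- which(obs[, j] & is.finite(scaled[i, ]))
      if (!length(donors)) {
        stop("no donor observes feature ", table$feature_names[j],
             " for sample ", table$sample_ids[i])
      }
      ord <- donors[order(scaled[i, donors], donors)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(x[nn, j])
    }
  }
  feature_table(out, feature_names = table$feature_names,
                feature_kinds = table$feature_kinds,
                sample_ids = table$sample_ids, levels = table$levels)
}

#' Stratified train/validation split
#'
#' Splits a labeled dataset into disjoint train and validation parts with
#' per-class validation counts `round(fraction * class size)`
#' (half-away-from-zero), adjusting the larger class so the global validation
#' total equals `round(fraction * n)`. Deterministic for a fixed seed.
#'
#' @param dataset a [labeled_dataset()].
#' @param validation_fraction real in (0, 1); default 0.25.
#' @param seed integer seed.
#' @return a list of class `split_pair` with elements `train`, `validation`,
#'   `fraction`, `seed`.
#' @export
stratified_split <- function(dataset, validation_fraction = 0.25, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  y <- dataset$labels
  n <- length(y)
  cls_n <- c(sum(y == 0), sum(y == 1))
  if (any(cls_n < 2)) stop("each class needs at least 2 samples to split")
  total <- round_half_up(validation_fraction * n)
  per_cls <- round_half_up(validation_fraction * cls_n)
  # adjust the larger class to hit the global total exactly
  excess <- sum(per_cls) - total
  adj <- which.max(cls_n)
  per_cls[adj] <- per_cls[adj] - excess
  per_cls <- pmin(pmax(per_cls, 1L), cls_n - 1L)

  val_idx <- with_seed(derive_seed(seed, 75L, 25L), {
    unlist(lapply(0:1, function(cl) {
      pool <- which(y == cl)
      pool[sample.int(length(pool), per_cls[cl + 1])]
    }))
  })
  val_idx <- sort(val_idx)
  tr_idx <- setdiff(seq_len(n), val_idx)
  structure(
    list(train = labeled_dataset(ft_rows(dataset$table, tr_idx), y[tr_idx],
                                 dataset$profile_id),
         validation = labeled_dataset(ft_rows(dataset$table, val_idx),
                                      y[val_idx], dataset$profile_id),
         fraction = validation_fraction, seed = seed),
    class = "split_pair"
  )
}
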