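# Operator layer: feature transformers, constructors and selectors with a
# strict fit-on-train / apply-to-any contract. Internally operators work on
# plain numeric matrices; op_fit() learns state from the training matrix
# (plus labels for supervised selectors and the stacking estimator) and
# op_apply() replays the learned transformation on any matrix with the same
# feature count. Applying never re-fits and never mutates learned state.

op_kinds <- function() {
  c(standard_scaler = "transformer", min_max_scaler = "transformer",
    max_abs_scaler = "transformer", binarizer = "transformer",
    normalizer = "transformer", polynomial_features = "constructor",
    pca = "transformer", ica = "transformer", nystroem = "transformer",
    rbf_sampler = "transformer", zero_counts = "constructor",
    stacking_estimator = "constructor", one_hot_encoder = "constructor",
    feature_agglomeration = "transformer",
    variance_threshold = "selector", select_percentile = "selector",
    select_fwe = "selector", rfe = "selector", select_from_model = "selector")
}

op_is_selector <- function(name) op_kinds()[[name]] == "selector"

op_fit <- function(name, params, x, y = NULL, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  state <- with_seed(derive_seed(seed, nchar(name), 7L),
                     op_fitters[[name]](x, y, params))
  structure(list(name = name, params = params, state = state,
                 n_features = ncol(x)),
            class = "pipetree_op")
}

op_apply <- function(fit, x) {
  stopifnot(inherits(fit, "pipetree_op"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != fit$n_features) stop("feature count mismatch at apply")
  out <- op_appliers[[fit$name]](fit$state, x, fit$params)
  colnames(out) <- paste0("x", seq_len(ncol(out)))
  out
}

# population variance/sd (divide by n), the convention used throughout
pop_var <- function(x) colMeans(sweep(x, 2, colMeans(x))^2)

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# extra-trees impurity importance, the internal estimator for RFE and
# select-from-model
et_importance <- function(x, y, seed) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  m <- ranger::ranger(x = as.data.frame(x), y = factor(y, levels = 0:1),
                      num.trees = 50, splitrule = "extratrees",
                      num.random.splits = 1, replace = FALSE,
                      sample.fraction = 1, importance = "impurity",
                      num.threads = 1, seed = seed)
  imp <- m$variable.importance
  imp[paste0("f", seq_len(ncol(x)))]
}

op_fitters <- list(
  standard_scaler = function(x, y, p) {
    sd <- sqrt(pop_var(x))
    sd[sd == 0] <- 1 # zero-variance feature: scale treated as 1
    list(mu = colMeans(x), sd = sd)
  },
  min_max_scaler = function(x, y, p) {
    mn <- apply(x, 2, min)
    rg <- apply(x, 2, max) - mn
    rg[rg == 0] <- 1
    list(mn = mn, rg = rg)
  },
  max_abs_scaler = function(x, y, p) {
    ma <- apply(abs(x), 2, max)
    ma[ma == 0] <- 1
    list(ma = ma)
  },
  binarizer = function(x, y, p) list(),
  normalizer = function(x, y, p) list(),
  polynomial_features = function(x, y, p) list(d = ncol(x)),
  pca = function(x, y, p) {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- max(1L, floor((p$n_components %||% 1) * ncol(pc$rotation)))
    list(center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE])
  },
  ica = function(x, y, p) {
    k <- min(nrow(x) - 1, ncol(x))
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    eg <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
    keep <- which(eg$values > 1e-10)[seq_len(min(k, sum(eg$values > 1e-10)))]
    wh <- eg$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[keep]), length(keep))
    z <- xc %*% wh # whitened
    k <- ncol(z)
    # symmetric fastICA fixed point, logcosh nonlinearity
    W <- matrix(stats::rnorm(k * k), k, k)
    sym_decorrelate <- function(W) {
      s <- eigen(W %*% t(W), symmetric = TRUE)
      s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), k) %*%
        t(s$vectors) %*% W
    }
    W <- sym_decorrelate(W)
    tol <- p$tol %||% 1e-4
    for (it in seq_len(200)) {
      wx <- z %*% t(W)
      g <- tanh(wx)
      gp <- 1 - g^2
      W1 <- t(g) %*% z / nrow(z) - diag(colMeans(gp), k) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) break
    }
    list(mu = mu, unmix = wh %*% t(W))
  },
  nystroem = function(x, y, p) {
    m <- min(p$n_components %||% 10, nrow(x))
    gamma <- p$gamma %||% (1 / ncol(x))
    land <- x[sample.int(nrow(x), m), , drop = FALSE]
    K <- rbf_kernel(land, land, gamma)
    eg <- eigen(K, symmetric = TRUE)
    keep <- eg$values > 1e-10
    basis <- eg$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[keep]), sum(keep))
    list(landmarks = land, gamma = gamma, basis = basis)
  },
  rbf_sampler = function(x, y, p) {
    D <- p$n_components %||% 100
    gamma <- p$gamma %||% 1
    list(W = matrix(stats::rnorm(ncol(x) * D, sd = sqrt(2 * gamma)),
                    ncol(x), D),
         b = stats::runif(D, 0, 2 * pi))
  },
  zero_counts = function(x, y, p) list(),
  stacking_estimator = function(x, y, p) {
    if (is.null(y)) stop("stacking estimator needs training labels")
    clf_fit(p$estimator, x, y, p$est_params %||% list(),
            seed = sample.int(2^31 - 2, 1))
  },
  one_hot_encoder = function(x, y, p) {
    maxl <- p$max_levels %||% 10
    enc <- lapply(seq_len(ncol(x)), function(j) {
      u <- sort(unique(x[, j]))
      if (length(u) <= maxl) u else NULL
    })
    list(enc = enc)
  },
  feature_agglomeration = function(x, y, p) {
    k <- min(p$n_clusters %||% 2, ncol(x))
    if (ncol(x) == 1) return(list(cluster = 1L, k = 1L))
    hc <- stats::hclust(stats::dist(t(x)), method = p$linkage %||% "ward.D2")
    list(cluster = stats::cutree(hc, k = k), k = k)
  },
  variance_threshold = function(x, y, p) {
    keep <- unname(which(pop_var(x) > (p$threshold %||% 0)))
    if (!length(keep)) stop("empty feature set")
    list(idx = keep)
  },
  select_percentile = function(x, y, p) {
    sc <- f_scores(x, y)$stat
    k <- max(1L, floor((p$percentile %||% 50) / 100 * ncol(x)))
    list(idx = sort(order(-sc, seq_along(sc))[seq_len(k)]))
  },
  select_fwe = function(x, y, p) {
    alpha <- p$alpha %||% 0.05
    pv <- f_scores(x, y)$p
    keep <- unname(which(pv < alpha / ncol(x))) # Bonferroni FWE control
    if (!length(keep)) stop("empty feature set")
    list(idx = keep)
  },
  rfe = function(x, y, p) {
    step <- p$step %||% 0.5
    target <- ceiling(ncol(x) / 2) # reduce the feature set in half
    idx <- seq_len(ncol(x))
    while (length(idx) > target) {
      imp <- et_importance(x[, idx, drop = FALSE], y,
                           seed = sample.int(.Machine$integer.max, 1))
      n_drop <- min(max(1L, floor(step * length(idx))),
                    length(idx) - target)
      drop <- order(imp, -seq_along(imp))[seq_len(n_drop)]
      idx <- idx[-drop]
    }
    list(idx = sort(idx))
  },
  select_from_model = function(x, y, p) {
    imp <- et_importance(x, y, seed = sample.int(.Machine$integer.max, 1))
    imp <- imp / max(sum(imp), 1e-12)
    keep <- unname(which(imp >= (p$threshold %||% (1 / ncol(x)))))
    if (!length(keep)) stop("empty feature set")
    list(idx = keep)
  }
)

op_appliers <- list(
  standard_scaler = function(s, x, p) sweep(sweep(x, 2, s$mu), 2, s$sd, "/"),
  min_max_scaler = function(s, x, p) sweep(sweep(x, 2, s$mn), 2, s$rg, "/"),
  max_abs_scaler = function(s, x, p) sweep(x, 2, s$ma, "/"),
  binarizer = function(s, x, p) (x > (p$threshold %||% 0)) * 1,
  normalizer = function(s, x, p) {
    nrm <- switch(p$norm %||% "l2",
                  l1 = rowSums(abs(x)),
                  l2 = sqrt(rowSums(x^2)),
                  max = apply(abs(x), 1, max))
    nrm[nrm == 0] <- 1
    x / nrm
  },
  polynomial_features = function(s, x, p) {
    d <- ncol(x)
    pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    cbind(x, x[, pairs[, 1], drop = FALSE] * x[, pairs[, 2], drop = FALSE])
  },
  pca = function(s, x, p) sweep(x, 2, s$center) %*% s$rotation,
  ica = function(s, x, p) sweep(x, 2, s$mu) %*% s$unmix,
  nystroem = function(s, x, p) {
    rbf_kernel(x, s$landmarks, s$gamma) %*% s$basis
  },
  rbf_sampler = function(s, x, p) {
    sqrt(2 / ncol(s$W)) * cos(sweep(x %*% s$W, 2, s$b, "+"))
  },
  zero_counts = function(s, x, p) {
    cbind(x, rowSums(x == 0), rowSums(x != 0))
  },
  stacking_estimator = function(s, x, p) {
    pr <- clf_predict(s, x)
    p1 <- pr$score
    if (any(p1 < 0 | p1 > 1)) p1 <- 1 / (1 + exp(-p1)) # decision values
    cbind(x, pr$class, 1 - p1, p1)
  },
  one_hot_encoder = function(s, x, p) {
    keep <- which(vapply(s$enc, is.null, logical(1)))
    blocks <- lapply(seq_along(s$enc), function(j) {
      u <- s$enc[[j]]
      if (is.null(u)) return(NULL)
      do.call(cbind, lapply(u, function(v) (x[, j] == v) * 1))
    })
    cbind(x[, keep, drop = FALSE], do.call(cbind, Filter(Negate(is.null),
                                                         blocks)))
  },
  feature_agglomeration = function(s, x, p) {
    do.call(cbind, lapply(seq_len(s$k), function(cl) {
      rowMeans(x[, s$cluster == cl, drop = FALSE])
    }))
  },
  variance_threshold = function(s, x, p) x[, s$idx, drop = FALSE],
  select_percentile = function(s, x, p) x[, s$idx, drop = FALSE],
  select_fwe = function(s, x, p) x[, s$idx, drop = FALSE],
  rfe = function(s, x, p) x[, s$idx, drop = FALSE],
  select_from_model = function(s, x, p) x[, s$idx, drop = FALSE]
)

# one-way ANOVA F statistic and p-value per feature for a binary grouping
f_scores <- function(x, y) {
  if (is.null(y)) stop("supervised selector needs training labels")
  n <- nrow(x)
  g0 <- y == 0
  n0 <- sum(g0)
  n1 <- n - n0
  m0 <- colMeans(x[g0, , drop = FALSE])
  m1 <- colMeans(x[!g0, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ssw <- colSums(sweep(x[g0, , drop = FALSE], 2, m0)^2) +
    colSums(sweep(x[!g0, , drop = FALSE], 2, m1)^2)
  stat <- (ssb / 1) / (ssw / pmax(n - 2, 1))
  stat[ssw == 0 & ssb > 0] <- Inf
  stat[ssw == 0 & ssb == 0] <- 0
  list(stat = stat, p = stats::pf(stat, 1, n - 2, lower.tail = FALSE))
}

#' Fit a transformer/constructor on training data and apply it
#'
#' Learns the operator's statistics (means, scales, components, internal
#' classifier, ...) from `train` only and applies the learned transformation
#' to `apply_to`. Column counts may change (polynomial expansion, PCA,
#' one-hot, zero counts, stacking); feature names are regenerated
#' deterministically as `x1..xd`.
#'
#' @param name operator name (see [full_configuration()]).
#' @param params named list of hyperparameter values.
#' @param train a [feature_table()] or [labeled_dataset()] (labels are needed
#'   by the stacking estimator).
#' @param apply_to a `feature_table` sharing `train`'s feature set; defaults
#'   to `train` itself.
#' @param seed integer seed for stochastic operators.
#' @return a `feature_table` of transformed values.
#' @export
fit_apply_transformer <- function(name, params = list(), train,
                                  apply_to = NULL, seed = 1) {
  ty <- NULL
  if (inherits(train, "labeled_dataset")) {
    ty <- train$labels
    train <- train$table
  }
  stopifnot(inherits(train, "feature_table"))
  if (op_is_selector(name)) stop("use fit_apply_selector() for selectors")
  if (is.null(apply_to)) apply_to <- train
  f <- op_fit(name, params, train$values, ty, seed)
  out <- op_apply(f, apply_to$values)
  feature_table(out, sample_ids = apply_to$sample_ids)
}

#' Fit a feature selector on labeled training data and apply it
#'
#' @inheritParams fit_apply_transformer
#' @param train a [labeled_dataset()] (supervised selectors use its labels).
#' @return a list with `table` (the column-subset `feature_table`) and
#'   `selected` (the kept column indices).
#' @export
fit_apply_selector <- function(name, params = list(), train, apply_to = NULL,
                               seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (!op_is_selector(name)) stop(name, " is not a selector")
  if (is.null(apply_to)) apply_to <- train$table
  f <- op_fit(name, params, train$table$values, train$labels, seed)
  idx <- f$state$idx
  list(table = ft_select(apply_to, idx), selected = idx)
}

#' Append stacked-classifier features
#'
#' Feature constructor that fits an internal classifier on the training data
#' and appends its predicted class and per-class probabilities (three columns
#' for binary labels) to the applied table.
#'
#' @param classifier_name internal classifier name.
#' @param params hyperparameter values for the internal classifier.
#' @inheritParams fit_apply_selector
#' @return a `feature_table` with `d + 3` columns.
#' @export
construct_stacked_features <- function(classifier_name, params = list(),
                                       train, apply_to = NULL, seed = 1) {
  fit_apply_transformer("stacking_estimator",
                        list(estimator = classifier_name,
                             est_params = params),
                        train, apply_to, seed)
}
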