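# Internal classifier layer. Every classifier exposes
#   clf_fit(name, x, y, params, seed)  -> fitted model object
#   clf_predict(model, x)              -> list(class = 0/1 vector,
#                                              score = class-1 score)
# with x a plain numeric matrix and y an integer 0/1 vector. Scores are
# probabilities where the model provides them, otherwise monotone decision
# values, so they are usable for ROC/PR curves either way.

clf_names <- function() {
  c("logistic_regression", "decision_tree", "random_forest", "extra_trees",
    "gradient_boosting", "k_neighbors", "linear_svc", "mlp",
    "gaussian_nb", "bernoulli_nb", "multinomial_nb")
}

clf_fit <- function(name, x, y, params = list(), seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  # positional feature matching: internal models always see f1..fd
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  fitter <- switch(name,
    logistic_regression = fit_lr,
    decision_tree = fit_dt,
    random_forest = fit_rf,
    extra_trees = fit_et,
    gradient_boosting = fit_gb,
    k_neighbors = fit_knn,
    linear_svc = fit_lsvc,
    mlp = fit_mlp,
    gaussian_nb = fit_gnb,
    bernoulli_nb = fit_bnb,
    multinomial_nb = fit_mnb,
    stop("unknown classifier: ", name)
  )
  model <- with_seed(derive_seed(seed, nchar(name)), fitter(x, y, params))
  structure(list(name = name, params = params, model = model,
                 n_features = ncol(x)), class = "pipetree_clf")
}

clf_predict <- function(fit, x) {
  stopifnot(inherits(fit, "pipetree_clf"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != fit$n_features) stop("feature count mismatch at predict")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  pred <- switch(fit$name,
    logistic_regression = pred_lr,
    decision_tree = pred_dt,
    random_forest = pred_ranger,
    extra_trees = pred_ranger,
    gradient_boosting = pred_gb,
    k_neighbors = pred_knn,
    linear_svc = pred_lsvc,
    mlp = pred_mlp,
    gaussian_nb = pred_nb,
    bernoulli_nb = pred_nb,
    multinomial_nb = pred_nb
  )(fit$model, x)
  pred$class <- as.integer(pred$class)
  pred
}

# ---- penalized logistic regression (glmnet) --------------------------------

fit_lr <- function(x, y, p) {
  C <- p$C %||% 1
  alpha <- if (identical(p$penalty %||% "l2", "l1")) 1 else 0
  xx <- if (ncol(x) == 1) cbind(x, `.pad` = 0) else x # glmnet needs >= 2 cols
  # extreme C values on badly-scaled inputs can exhaust glmnet's iteration
  # budget; the partial fit it returns is still a usable (if weak) model,
  # and selection handles weak pipelines through their fitness
  m <- suppressWarnings(
    glmnet::glmnet(xx, factor(y, levels = 0:1), family = "binomial",
                   alpha = alpha, lambda = 1 / (nrow(x) * C),
                   standardize = FALSE))
  list(m = m, padded = ncol(x) == 1)
}

pred_lr <- function(model, x) {
  if (model$padded) x <- cbind(x, `.pad` = 0)
  pr <- as.numeric(stats::predict(model$m, newx = x, type = "response"))
  list(class = pr > 0.5, score = pr)
}

# ---- decision tree (rpart) -------------------------------------------------

fit_dt <- function(x, y, p) {
  df <- data.frame(.y = factor(y, levels = 0:1), x, check.names = FALSE)
  rpart::rpart(.y ~ ., df, method = "class",
               control = rpart::rpart.control(
                 maxdepth = p$max_depth %||% 10,
                 minsplit = p$min_samples_split %||% 2,
                 minbucket = p$min_samples_leaf %||% 1,
                 cp = 0, xval = 0))
}

pred_dt <- function(model, x) {
  pr <- stats::predict(model, as.data.frame(x), type = "prob")[, "1"]
  list(class = pr > 0.5, score = pr)
}

# ---- random forest / extra trees (ranger) ----------------------------------

ranger_common <- function(x, y, p, extra) {
  d <- ncol(x)
  frac <- p$max_features %||% (sqrt(d) / d)
  mtry <- max(1L, min(d, floor(frac * d)))
  args <- list(x = as.data.frame(x), y = factor(y, levels = 0:1),
               num.trees = p$n_estimators %||% 100,
               mtry = mtry,
               min.node.size = p$min_samples_leaf %||% 1,
               probability = TRUE, num.threads = 1,
               seed = sample.int(.Machine$integer.max, 1))
  do.call(ranger::ranger, c(args, extra))
}

fit_rf <- function(x, y, p) {
  boot <- p$bootstrap %||% TRUE
  ranger_common(x, y, p, list(replace = boot,
                              sample.fraction = if (boot) 1 else 0.632))
}

fit_et <- function(x, y, p) {
  ranger_common(x, y, p, list(splitrule = "extratrees",
                              num.random.splits = 1,
                              replace = FALSE, sample.fraction = 1))
}

pred_ranger <- function(model, x) {
  pr <- stats::predict(model, data = as.data.frame(x),
                       num.threads = 1)$predictions[, "1"]
  list(class = pr > 0.5, score = pr)
}

# ---- gradient tree boosting (xgboost) --------------------------------------

fit_gb <- function(x, y, p) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "binary:logistic",
                 max_depth = p$max_depth %||% 3,
                 eta = p$learning_rate %||% 0.1,
                 subsample = p$subsample %||% 1,
                 nthread = 1,
                 seed = sample.int(.Machine$integer.max, 1))
  xgboost::xgb.train(params = params, data = dm,
                     nrounds = p$n_estimators %||% 100, verbose = 0)
}

pred_gb <- function(model, x) {
  pr <- stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
  list(class = pr > 0.5, score = pr)
}

# ---- k nearest neighbours (class) ------------------------------------------

fit_knn <- function(x, y, p) {
  list(x = x, y = factor(y, levels = 0:1),
       k = min(p$n_neighbors %||% 5, nrow(x)))
}

pred_knn <- function(model, x) {
  # fraction of class-1 votes among the k neighbours as the score
  pred <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
  pwin <- attr(pred, "prob")
  score <- ifelse(pred == "1", pwin, 1 - pwin)
  list(class = pred == "1", score = score)
}

# ---- linear support-vector classifier (e1071) ------------------------------

fit_lsvc <- function(x, y, p) {
  m <- e1071::svm(x, factor(y, levels = 0:1), kernel = "linear",
                  cost = p$C %||% 1, scale = FALSE)
  list(m = m)
}

pred_lsvc <- function(model, x) {
  pv <- stats::predict(model$m, x, decision.values = TRUE)
  dv <- as.numeric(attr(pv, "decision.values"))
  dname <- colnames(attr(pv, "decision.values"))[1]
  if (identical(dname, "0/1")) dv <- -dv
  list(class = pv == "1", score = dv)
}

# ---- multilayer perceptron (nnet) ------------------------------------------

fit_mlp <- function(x, y, p) {
  nnet::nnet(x, y, size = p$hidden_units %||% 10,
             decay = p$alpha %||% 1e-4, maxit = 100,
             entropy = TRUE, trace = FALSE, MaxNWts = 5000)
}

pred_mlp <- function(model, x) {
  pr <- as.numeric(stats::predict(model, x))
  list(class = pr > 0.5, score = pr)
}

# ---- naive Bayes family (in-package; see vignette) -------------------------
# Gaussian, Bernoulli and multinomial event models with Laplace/Lidstone
# smoothing. The Bernoulli variant binarizes its input at a threshold
# (default 0.0, strictly greater-than), so standard-scaled continuous
# features become mean-binarized indicators.

nb_priors <- function(y, fit_prior) {
  n <- length(y)
  if (fit_prior) c(mean(y == 0), mean(y == 1)) else c(0.5, 0.5)
}

fit_gnb <- function(x, y, p) {
  eps <- 1e-9 * max(apply(x, 2, stats::var), 1e-12)
  stats_by <- lapply(0:1, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mu = colMeans(xc),
         var = apply(xc, 2, function(v) mean((v - mean(v))^2)) + eps)
  })
  list(type = "gaussian", stats = stats_by, prior = nb_priors(y, TRUE))
}

fit_bnb <- function(x, y, p) {
  thr <- p$threshold %||% 0
  alpha <- p$alpha %||% 1
  xb <- (x > thr) * 1
  prob <- lapply(0:1, function(cl) {
    xc <- xb[y == cl, , drop = FALSE]
    (colSums(xc) + alpha) / (nrow(xc) + 2 * alpha)
  })
  list(type = "bernoulli", threshold = thr, prob = prob,
       prior = nb_priors(y, p$fit_prior %||% TRUE))
}

fit_mnb <- function(x, y, p) {
  if (any(x < 0)) stop("multinomial naive Bayes requires non-negative input")
  alpha <- p$alpha %||% 1
  theta <- lapply(0:1, function(cl) {
    cs <- colSums(x[y == cl, , drop = FALSE]) + alpha
    cs / sum(cs)
  })
  list(type = "multinomial", theta = theta,
       prior = nb_priors(y, p$fit_prior %||% TRUE))
}

nb_posterior <- function(logl0, logl1, prior) {
  a <- logl0 + log(prior[1])
  b <- logl1 + log(prior[2])
  m <- pmax(a, b)
  p1 <- exp(b - m) / (exp(a - m) + exp(b - m))
  list(class = p1 > 0.5, score = p1)
}

pred_nb <- function(model, x) {
  switch(model$type,
    gaussian = {
      ll <- lapply(model$stats, function(s) {
        rowSums(t(-0.5 * (t(x) - s$mu)^2 / s$var - 0.5 * log(2 * pi * s$var)))
      })
      nb_posterior(ll[[1]], ll[[2]], model$prior)
    },
    bernoulli = {
      xb <- (x > model$threshold) * 1
      ll <- lapply(model$prob, function(pr) {
        as.numeric(xb %*% log(pr) + (1 - xb) %*% log(1 - pr))
      })
      nb_posterior(ll[[1]], ll[[2]], model$prior)
    },
    multinomial = {
      if (any(x < 0)) stop("multinomial naive Bayes requires non-negative input")
      ll <- lapply(model$theta, function(th) as.numeric(x %*% log(th)))
      nb_posterior(ll[[1]], ll[[2]], model$prior)
    })
}
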