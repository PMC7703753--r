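test_that("simple transformers match their closed-form definitions", {
  row <- feature_table(matrix(c(3, 4), 1, 2))
  expect_equal(unname(fit_apply_transformer("normalizer", list(norm = "l2"),
                                            row)$values[1, ]),
               c(0.6, 0.8))

  tri <- feature_table(matrix(c(-1.2, 0, 3.4), 3, 1))
  expect_equal(unname(fit_apply_transformer("binarizer",
                                            list(threshold = 0),
                                            tri)$values[, 1]),
               c(0, 0, 1)) # strictly greater than the threshold

  zc <- fit_apply_transformer("zero_counts", list(),
                              feature_table(matrix(c(0, 1.2, 0, 3), 1, 4)))
  expect_equal(unname(zc$values[1, 5:6]), c(2, 2))

  # standard scaler uses training mean 2 and population sd sqrt(2/3)
  train <- feature_table(matrix(c(1, 2, 3), 3, 1))
  out <- fit_apply_transformer("standard_scaler", list(), train,
                               feature_table(matrix(4, 1, 1)))
  expect_equal(unname(out$values[1, 1]), (4 - 2) / sqrt(2 / 3),
               tolerance = 1e-12)

  # zero-variance feature: scale treated as 1, no division by zero
  cst <- feature_table(cbind(c(5, 5, 5), c(1, 2, 3)))
  out2 <- fit_apply_transformer("standard_scaler", list(), cst)
  expect_true(all(is.finite(out2$values)))
  expect_equal(unname(out2$values[, 1]), c(0, 0, 0))
})

test_that("constructor column counts follow the documented formulas", {
  d <- 5L
  tab <- rand_table(20, d, seed = 3)
  poly <- fit_apply_transformer("polynomial_features", list(), tab)
  expect_identical(ncol(poly$values), as.integer(d + d * (d + 1) / 2))

  zc <- fit_apply_transformer("zero_counts", list(), tab)
  expect_identical(ncol(zc$values), d + 2L)

  ds <- rand_dataset(30, d, seed = 4)
  se <- construct_stacked_features("logistic_regression",
                                   list(C = 1, penalty = "l2"), ds)
  expect_identical(ncol(se$values), d + 3L)
  # appended probability columns sum to one
  pcols <- se$values[, d + 2:3]
  expect_equal(unname(rowSums(pcols)), rep(1, 30), tolerance = 1e-9)
})

test_that("stacking a majority-class predictor appends a constant column", {
  set.seed(5)
  n <- 50
  y <- c(rep(1, 40), rep(0, 10))
  ds <- labeled_dataset(rand_table(n, 3, 6), y)
  # k = n nearest neighbours vote with the global majority everywhere
  se <- construct_stacked_features("k_neighbors", list(n_neighbors = 49), ds)
  expect_true(all(se$values[, 4] == 1))
})

test_that("selectors keep the right columns and learn from train only", {
  # variance threshold 0 removes exactly the constant column
  v <- cbind(a = rnorm(20), b = rep(2, 20), c = rnorm(20))
  ds <- labeled_dataset(feature_table(v), rep_len(0:1, 20))
  sel <- fit_apply_selector("variance_threshold", list(threshold = 0), ds)
  expect_identical(sel$selected, c(1L, 3L))

  # percentile 50 on 10 features keeps exactly 5
  ds10 <- rand_dataset(40, 10, seed = 8)
  sel2 <- fit_apply_selector("select_percentile", list(percentile = 50), ds10)
  expect_length(sel2$selected, 5)

  # selecting everything away errors
  expect_error(
    fit_apply_selector("variance_threshold", list(threshold = 1e9), ds10),
    "empty feature set")
})

test_that("RFE with halving retains a planted label-copy feature", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    y <- rep_len(0:1, n)
    x <- cbind(matrix(rnorm(n * 7), n, 7), y)
    colnames(x) <- c(paste0("f", 1:7), "copy")
    ds <- labeled_dataset(feature_table(x), y)
    sel <- fit_apply_selector("rfe", list(step = 0.5), ds, seed = seed)
    expect_length(sel$selected, 4) # 8 features reduced in half
    if (8L %in% sel$selected) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("operators never refit at apply time", {
  ds <- rand_dataset(30, 4, seed = 11)
  other <- rand_table(10, 4, seed = 12)
  for (nm in c("standard_scaler", "min_max_scaler", "max_abs_scaler", "pca",
               "feature_agglomeration", "rbf_sampler", "nystroem")) {
    f <- pipetree:::op_fit(nm, list(), ds$table$values, ds$labels, seed = 5)
    a1 <- pipetree:::op_apply(f, other$values)
    # applying to anything else in between must not change the learned state
    pipetree:::op_apply(f, ds$table$values)
    a2 <- pipetree:::op_apply(f, other$values)
    expect_identical(a1, a2, label = nm)
  }
})

test_that("Bernoulli naive Bayes at threshold 0 ignores positive rescaling", {
  set.seed(13)
  n <- 80
  y <- rep_len(0:1, n)
  x <- matrix(rnorm(n * 5), n, 5)
  f <- pipetree:::clf_fit("bernoulli_nb", x, y, list(alpha = 1), seed = 1)
  scale <- diag(runif(5, 0.2, 9))
  p1 <- pipetree:::clf_predict(pipetree:::clf_fit("bernoulli_nb", x %*% scale,
                                                  y, list(alpha = 1),
                                                  seed = 1), x %*% scale)
  p0 <- pipetree:::clf_predict(f, x)
  expect_identical(p0$class, p1$class)
})

test_that("Gaussian naive Bayes agrees with an independent implementation", {
  set.seed(14)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 3, mean = y), n, 3)
  xt <- matrix(rnorm(30, mean = 0.5), 10, 3)
  ours <- pipetree:::clf_predict(
    pipetree:::clf_fit("gaussian_nb", x, y, list(), seed = 1), xt)
  ref <- e1071::naiveBayes(data.frame(x), factor(y, levels = 0:1))
  ref_cls <- as.integer(as.character(predict(ref, data.frame(xt))))
  expect_identical(ours$class, ref_cls)
})
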