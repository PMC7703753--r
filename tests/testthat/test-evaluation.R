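test_that("grid size is the product of domain sizes", {
  expect_equal(grid_size(list(a = 1:10, b = 1:10, c = 1:10, d = 1:10,
                              e = 1:10)), 1e5)
  expect_equal(grid_size(list()), 1)
  expect_equal(grid_size(list(a = 1:3)), 3)
})

# exhaustive enumeration of ordered arrangements of <= p distinct items
arrangements_oracle <- function(p) {
  count <- 1 # empty chain
  for (k in seq_len(p)) count <- count + prod(p:(p - k + 1))
  count
}

test_that("pre-processor search space counts ordered arrangements", {
  expect_equal(preprocessor_search_space(7, 0), 7)
  # p = 2: {empty, A, B, AB, BA}
  expect_equal(preprocessor_search_space(1, 2), 5)
  for (p in 1:6) {
    expect_equal(preprocessor_search_space(1, p), arrangements_oracle(p))
  }
  # 10 pre-processors on a 100 000-combination grid
  expect_equal(preprocessor_search_space(1e5, 10), 986410100000)
})

test_that("grid search enumerates the Cartesian grid and reports complexity", {
  ds <- separable_dataset(60, seed = 21)
  val <- separable_dataset(24, seed = 22)
  gs <- grid_search("gaussian_nb", list(), ds, n_folds = 3, seed = 1,
                    validation = val)
  expect_identical(gs$n_evaluated, 1L)
  expect_identical(gs$complexity, 1L)
  expect_gt(gs$report_validation$balanced_accuracy, 0.9)

  gs2 <- grid_search("decision_tree",
                     list(max_depth = c(2, 4), min_samples_split = c(2, 5, 10)),
                     ds, n_folds = 3, seed = 1)
  expect_identical(gs2$n_evaluated, 6L)

  # fixed pre-processor chain: scaler + RFE before the classifier -> 3
  gs3 <- grid_search("logistic_regression", list(C = c(0.1, 1)), ds,
                     n_folds = 3, seed = 1,
                     preprocessors = list(
                       list(name = "standard_scaler", params = list()),
                       list(name = "rfe", params = list(step = 0.5))))
  expect_identical(gs3$complexity, 3L)

  expect_error(grid_search("gaussian_nb", NULL, ds), "param_grid")
})

test_that("permutation importance zeroes ignored features and finds signal", {
  set.seed(23)
  n <- 120
  y <- rep_len(0:1, n)
  x <- cbind(sig = rnorm(n, 3 * y), cst = rep(1, n), noise = rnorm(n))
  ds <- labeled_dataset(feature_table(x), y)
  # variance threshold removes the constant column, then Gaussian NB:
  # predictions cannot depend on `cst`
  tree <- parse_pipeline("GNB()<-VT(threshold=0)<-DATA")
  fp <- fit_pipeline(tree, ds, seed = 1)
  pfi <- permutation_importance(fp, ds, n_repeats = 20, seed = 2)
  expect_equal(pfi$decreases[, "cst"], rep(0, 20))
  expect_identical(pfi$table$feature[1], "sig")
  expect_equal(pfi$table$mean_decrease[1],
               mean(pfi$decreases[, "sig"]), tolerance = 1e-12)
  # scores are bounded: no single decrease exceeds the baseline
  expect_true(all(pfi$decreases <= pfi$baseline_score + 1e-12))

  # single-feature threshold model: permuting the lone feature drives the
  # score to chance, so the mean decrease approaches baseline - 0.5
  one <- labeled_dataset(feature_table(x[, "sig", drop = FALSE]), y)
  fp1 <- fit_pipeline(bare_tree("decision_tree",
                                list(max_depth = 1, min_samples_split = 2,
                                     min_samples_leaf = 1)), one, seed = 3)
  pfi1 <- permutation_importance(fp1, one, n_repeats = 100, seed = 4)
  b <- pfi1$baseline_score
  se3 <- 3 * pfi1$table$sd_decrease[1] / sqrt(100)
  expect_lt(abs(pfi1$table$mean_decrease[1] - (b - 0.5)), se3 + 0.02)

  expect_error(permutation_importance(fp, ds, n_repeats = 0), "positive")
})

test_that("pfi ordering is stable for a fixed seed", {
  ds <- rand_dataset(60, 5, seed = 24)
  fp <- fit_pipeline(bare_tree("gaussian_nb"), ds, seed = 1)
  p1 <- permutation_importance(fp, ds, n_repeats = 5, seed = 9)
  p2 <- permutation_importance(fp, ds, n_repeats = 5, seed = 9)
  expect_identical(p1$table, p2$table)
})

test_that("head ablation strips pre-processors from the input end", {
  ds <- separable_dataset(80, seed = 25)
  val <- separable_dataset(30, seed = 26)
  tree <- parse_pipeline(paste0(
    "GNB()<-SS()<-NORM(norm=l2)<-MMS()<-ZC()<-DATA"))
  ab <- head_ablation(tree, ds, val, seed = 1)
  expect_identical(ab$table$complexity, 5:1)
  expect_identical(ab$table$n_removed, 0:4)
  # first removal takes the operator nearest the data leaf (ZC)
  expect_false(grepl("ZC", ab$table$pipeline[2]))
  expect_true(grepl("SS", ab$table$pipeline[4]))
  expect_identical(ab$table$pipeline[5], "GNB()<-DATA")

  # the unablated row equals a direct report of the full pipeline
  fp <- fit_pipeline(tree, ds, seed = pipetree:::derive_seed(1, 1))
  pr <- predict(fp, val)
  direct <- classification_report(val$labels, pr$class, pr$score)
  expect_identical(ab$reports[[1]]$validation$balanced_accuracy,
                   direct$balanced_accuracy)

  # bare classifier: a single row identical to its own report
  ab1 <- head_ablation(bare_tree("gaussian_nb"), ds, val, seed = 2)
  expect_identical(nrow(ab1$table), 1L)
})

test_that("removing a positive rescaler before threshold-0 binarization is a no-op", {
  set.seed(27)
  n <- 100
  y <- rep_len(0:1, n)
  x <- matrix(rnorm(n * 4, mean = 0.4 * y), n, 4)
  ds <- labeled_dataset(feature_table(x[1:70, ]), y[1:70])
  val <- labeled_dataset(feature_table(x[71:100, ]), y[71:100])
  tree <- parse_pipeline("BNB(alpha=1,fit_prior=TRUE)<-MAS()<-DATA")
  ab <- head_ablation(tree, ds, val, seed = 3)
  expect_identical(nrow(ab$table), 2L)
  expect_equal(ab$table$bal_acc_V[1], ab$table$bal_acc_V[2])
  expect_equal(ab$table$recall_V[1], ab$table$recall_V[2])
})
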