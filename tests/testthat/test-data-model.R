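test_that("CSV loading infers kinds, maps labels and validates the file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,smoker,grp,outcome",
               "a,61,1,x,yes",
               "b,48,0,y,no",
               "c,,1,x,yes",
               "d,55,0,z,no"), path)
  ds <- load_feature_table(path, label_column = "outcome")
  expect_s3_class(ds, "labeled_dataset")
  expect_identical(ds$labels, c(1L, 0L, 1L, 0L)) # "yes" sorts after "no"
  expect_identical(unname(ds$table$feature_kinds),
                   c("continuous", "binary", "categorical"))
  expect_true(is.na(ds$table$values["c", "age"]))
  # categorical level codes are 0-based and recoverable
  expect_identical(ds$table$levels$grp, c("x", "y", "z"))
  expect_identical(unname(ds$table$values[, "grp"]), c(0, 1, 0, 2))

  expect_error(load_feature_table(path, label_column = "nope"),
               "missing label column")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f,outcome", "a,1,yes", "b,2,no", "c,3,maybe"), path3)
  expect_error(load_feature_table(path3, label_column = "outcome"),
               "label not binary")

  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f,outcome", "a,1,yes", "a,2,no"), path4)
  expect_error(load_feature_table(path4, label_column = "outcome"),
               "duplicate sample ids")
})

test_that("samples with a missing label are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f,outcome", "a,1,yes", "b,2,", "c,3,no"), path)
  expect_message(ds <- load_feature_table(path, label_column = "outcome"),
                 "dropped")
  expect_identical(ds$table$sample_ids, c("a", "c"))
})

test_that("KNN imputation: identity, forced nearest neighbour, errors", {
  tab <- rand_table(6, 3, seed = 42)
  expect_identical(knn_impute(tab, 2)$values, tab$values)

  # sample A misses f3; B is strictly nearest on observed features
  v <- rbind(A = c(0, 0, NA), B = c(0.1, 0.1, 7), C = c(5, 5, -3))
  colnames(v) <- c("f1", "f2", "f3")
  tab2 <- feature_table(v)
  out <- knn_impute(tab2, k = 1)
  expect_equal(out$values["A", "f3"], 7)
  expect_identical(out$values[c("B", "C"), ], v[c("B", "C"), ])

  expect_error(knn_impute(tab2, 0), "positive")
  all_missing <- feature_table(rbind(c(NA, NA), c(1, 2), c(2, 1)))
  expect_error(knn_impute(all_missing, 1), "all features missing")
})

test_that("KNN imputation matches the exhaustive-distance oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(3:6, 1); d <- sample(2:4, 1)
    v <- matrix(rnorm(n * d), n, d)
    v[sample(length(v), 3)] <- NA
    if (any(rowSums(!is.na(v)) == 0)) next
    k <- sample(1:2, 1)
    tab <- feature_table(v)
    expect_equal(knn_impute(tab, k)$values, unname(knn_oracle(v, k)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("KNN imputation is idempotent", {
  set.seed(7)
  v <- matrix(rnorm(40), 10, 4)
  v[sample(40, 6)] <- NA
  once <- knn_impute(feature_table(v), 3)
  expect_identical(knn_impute(once, 3)$values, once$values)
})

test_that("stratified split honours per-class counts and determinism", {
  ds8 <- labeled_dataset(rand_table(8, 2, 1), rep(0:1, each = 4))
  sp <- stratified_split(ds8, 0.25, seed = 3)
  expect_identical(sum(sp$validation$labels == 0), 1L)
  expect_identical(sum(sp$validation$labels == 1), 1L)
  sp2 <- stratified_split(ds8, 0.25, seed = 3)
  expect_identical(sp$validation$table$sample_ids,
                   sp2$validation$table$sample_ids)

  # 925 samples at 0.25 -> 231 validation / 694 train
  ds925 <- labeled_dataset(rand_table(925, 2, 2), rep_len(0:1, 925))
  sp925 <- stratified_split(ds925, 0.25, seed = 1)
  expect_identical(length(sp925$validation$labels), 231L)
  expect_identical(length(sp925$train$labels), 694L)

  single <- labeled_dataset(rand_table(5, 2, 3), c(1, 0, 0, 0, 0))
  expect_error(stratified_split(single, 0.25, 1), "at least 2")
})

test_that("split is a partition across many seeds", {
  ds <- labeled_dataset(rand_table(50, 3, 9), rep_len(c(0, 0, 1), 50))
  ids <- sort(ds$table$sample_ids)
  for (seed in 1:1000) {
    sp <- stratified_split(ds, 0.3, seed = seed)
    tr <- sp$train$table$sample_ids
    va <- sp$validation$table$sample_ids
    expect_length(intersect(tr, va), 0)
    expect_identical(sort(c(tr, va)), ids)
  }
})
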