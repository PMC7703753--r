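test_that("default synthetic cohort has the expected shape", {
  gen <- generate_synthetic(synthetic_config(seed = 1))
  expect_identical(dim(gen$p1$table), c(925L, 100L))
  expect_identical(gen$p1$profile_id, "P1")
  expect_identical(gen$p2$profile_id, "P2")
  # the two binarizations of the same latent severity
  expect_identical(gen$p1$labels, as.integer(gen$truth$latent_class >= 1))
  expect_identical(gen$p2$labels, as.integer(gen$truth$latent_class == 2))
  expect_length(gen$truth$informative_idx, 15)
})

test_that("generation is deterministic in the seed", {
  g1 <- generate_synthetic(synthetic_config(seed = 7))
  g2 <- generate_synthetic(synthetic_config(seed = 7))
  expect_identical(g1$p1$table$values, g2$p1$table$values)
  g3 <- generate_synthetic(synthetic_config(seed = 8))
  expect_false(identical(g1$p1$table$values, g3$p1$table$values))
})

test_that("class counts match the configured proportions up to rounding", {
  for (seed in 1:5) {
    gen <- generate_synthetic(synthetic_config(n_samples = 500, seed = seed,
                                               missing_rate = 0))
    counts <- tabulate(gen$truth$latent_class + 1L, 3)
    expect_true(all(abs(counts - round(c(0.2, 0.2, 0.6) * 500)) <= 1))
  }
})

test_that("missingness hits metabolic columns at the configured rate only", {
  gen <- generate_synthetic(synthetic_config(seed = 3, missing_rate = 0.05))
  v <- gen$p1$table$values
  met <- v[, 1:73]
  clin <- v[, 74:100]
  expect_false(anyNA(clin))
  expect_lt(abs(mean(is.na(met)) - 0.05), 0.01)
})

test_that("zero effect size carries no learnable signal", {
  scores <- vapply(1:10, function(seed) {
    gen <- generate_synthetic(synthetic_config(n_samples = 300, seed = seed,
                                               effect_size = 0,
                                               missing_rate = 0))
    rec <- evaluate_cv(bare_tree("decision_tree",
                                 list(max_depth = 5, min_samples_split = 2,
                                      min_samples_leaf = 1)),
                       gen$p1, n_folds = 3, seed = seed)
    rec$mean_cv_balanced_accuracy
  }, 0)
  expect_lt(abs(mean(scores) - 0.5), 0.05)
})

test_that("degenerate class proportions are rejected", {
  expect_error(synthetic_config(class_proportions = c(0.5, 0.5, 0)),
               "degenerate")
  expect_error(synthetic_config(n_informative_metabolic = 100),
               "exceed")
})

test_that("XOR structure defeats linear models but not interaction learners", {
  lr_scores <- c(); et_scores <- c()
  for (seed in 1:5) {
    ds <- generate_xor_dataset(n = 1000, n_noise = 8, seed = seed)
    lr <- evaluate_cv(bare_tree("logistic_regression",
                                list(C = 1, penalty = "l2")),
                      ds, n_folds = 3, seed = seed)
    et <- evaluate_cv(parse_pipeline(
      "ET(n_estimators=25,max_features=1,min_samples_leaf=1)<-DATA"),
      ds, n_folds = 3, seed = seed)
    lr_scores <- c(lr_scores, lr$mean_cv_balanced_accuracy)
    et_scores <- c(et_scores, et$mean_cv_balanced_accuracy)
  }
  # logistic regression hovers at chance (finite-sample CV noise allowed)
  expect_lte(mean(lr_scores), 0.55)
  expect_true(all(lr_scores <= 0.58))
  expect_true(all(et_scores >= 0.9))
})

test_that("xor_pair plants the interaction pair in the cohort generator", {
  cfg <- synthetic_config(n_samples = 400, xor_pair = TRUE, seed = 5,
                          n_informative_metabolic = 0,
                          n_informative_clinical = 0, missing_rate = 0)
  gen <- generate_synthetic(cfg)
  expect_identical(gen$truth$xor_names, c("clin26", "clin27"))
  x <- gen$p1$table$values[, gen$truth$xor_idx]
  expect_true(all(x %in% 0:1))
  # the xor of the pair shifts the severity distribution
  xr <- as.integer(xor(x[, 1] == 1, x[, 2] == 1))
  p_by_group <- tapply(gen$p1$labels, xr, mean)
  expect_gt(p_by_group["1"], p_by_group["0"])
})

test_that("planted recovery fraction counts top-k overlap", {
  truth <- structure(list(informative_names = c("a", "b", "c")),
                     class = "synthetic_ground_truth")
  fake_pfi <- structure(list(table = data.frame(
    feature = c("a", "b", "c", "d"),
    mean_decrease = c(0.4, 0.3, 0.2, 0.1))), class = "pfi_result")
  expect_equal(planted_recovery_check(truth, fake_pfi, top_k = 3), 1)
  fake_pfi$table <- fake_pfi$table[4:1, ]
  expect_equal(planted_recovery_check(truth, fake_pfi, top_k = 1), 0)
})
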