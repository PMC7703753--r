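tiny_profiles <- function(seed = 31) {
  gen <- generate_synthetic(synthetic_config(n_samples = 160,
                                             n_metabolic = 10,
                                             n_clinical = 6,
                                             n_informative_metabolic = 3,
                                             n_informative_clinical = 2,
                                             correlation_block_size = 5,
                                             missing_rate = 0.03,
                                             seed = seed))
  list(P1 = gen$p1)
}

test_that("a single grid-search roster yields one complexity-1 row", {
  cfg <- experiment_config(roster = "gs_lr", n_folds = 3, pfi_repeats = 2,
                           seed = 5)
  bundle <- run_experiment(tiny_profiles(), cfg)
  models <- bundle$profiles$P1$models
  expect_identical(nrow(models), 1L)
  expect_identical(models$complexity, 1L)
  expect_true(models$best)
  expect_s3_class(bundle$profiles$P1$pfi, "pfi_result")
  expect_s3_class(bundle$profiles$P1$ablation, "ablation_table")
})

test_that("report bundles are bit-stable across reruns and written intact", {
  cfg <- experiment_config(roster = c("gs_lr", "gs_dt"), n_folds = 3,
                           pfi_repeats = 2, seed = 6)
  profiles <- tiny_profiles()
  out1 <- withr::local_tempdir()
  b1 <- run_experiment(profiles, cfg, out_dir = out1)
  b2 <- run_experiment(profiles, cfg)
  expect_identical(b1$profiles$P1$models, b2$profiles$P1$models)
  expect_true(verify_experiment(b1, profiles))

  expect_setequal(dir(out1), c("models_P1.tsv", "ablation_P1.tsv",
                               "pfi_P1.tsv", "confusion_P1.json", "run.log",
                               "config.json"))
  written <- read.delim(file.path(out1, "models_P1.tsv"))
  expect_identical(nrow(written), 2L)
  # refusing to overwrite without force
  expect_error(run_experiment(profiles, cfg, out_dir = out1),
               "not empty")
})

test_that("roster validation rejects unknown models", {
  expect_error(experiment_config(roster = "gs_svm"), "unknown roster")
  expect_error(experiment_config(roster = character(0)), "non-empty")
})
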