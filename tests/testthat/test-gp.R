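test_that("one-point crossover swaps subtrees and preserves validity", {
  # linear parents cut below the classifiers exchange whole bodies
  a <- parse_pipeline("GNB()<-SS()<-MMS()<-DATA")
  b <- parse_pipeline("BNB(alpha=1,fit_prior=TRUE)<-ZC()<-DATA")
  set.seed(1)
  seen <- character(0)
  for (i in 1:200) {
    off <- crossover(a, b, max_operators = 10)
    seen <- union(seen, serialize_pipeline(off[[1]]))
  }
  expect_true("GNB()<-ZC()<-DATA" %in% seen)

  # two bare classifiers: swapping can only exchange dataset leaves
  c1 <- bare_tree("gaussian_nb")
  c2 <- bare_tree("bernoulli_nb", list(alpha = 1, fit_prior = TRUE))
  off <- crossover(c1, c2)
  expect_identical(serialize_pipeline(off[[1]]), serialize_pipeline(c1))
  expect_identical(serialize_pipeline(off[[2]]), serialize_pipeline(c2))
})

test_that("crossover offspring always satisfy the invariants", {
  fc <- full_configuration()
  set.seed(2)
  for (i in 1:1000) {
    a <- random_pipeline(fc, 10)
    b <- random_pipeline(fc, 10)
    off <- crossover(a, b, max_operators = 10)
    expect_true(pipetree:::validate_pipeline(off[[1]], 10))
    expect_true(pipetree:::validate_pipeline(off[[2]], 10))
  }
})

test_that("mutation keeps trees valid and changes complexity by at most 1", {
  fc <- full_configuration()
  set.seed(3)
  for (i in 1:3000) {
    tree <- random_pipeline(fc, 10)
    mt <- mutate_pipeline(tree, fc, max_operators = 10)
    expect_true(pipetree:::validate_pipeline(mt, 10))
    expect_lte(abs(complexity(mt) - complexity(tree)), 1)
  }
})

test_that("mutation picks uniformly among applicable moves", {
  fc <- full_configuration()
  set.seed(4)
  # mid-size trees where all four moves are applicable
  moves <- character(0)
  for (i in 1:4000) {
    tree <- parse_pipeline("GNB()<-SS()<-NORM(norm=l2)<-DATA")
    moves <- c(moves, attr(mutate_pipeline(tree, fc, max_operators = 10), "move"))
  }
  tab <- table(factor(moves, levels = c("insert", "remove", "substitute",
                                        "resample")))
  expect_true(all(tab > 0))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("removal on a bare classifier falls back to another valid move", {
  fc <- full_configuration()
  set.seed(5)
  for (i in 1:200) {
    mt <- mutate_pipeline(bare_tree("gaussian_nb"), fc, max_operators = 10)
    expect_true(pipetree:::validate_pipeline(mt, 10))
    expect_false(identical(attr(mt, "move"), "remove"))
  }
})

make_cand <- function(fit, comp) {
  list(tree = bare_tree("gaussian_nb"),
       record = structure(list(mean_cv_balanced_accuracy = fit,
                               per_fold_scores = fit, complexity = comp,
                               valid = is.finite(fit)),
                          class = "fitness_record"))
}

test_that("tournament drops the worst, then prefers parsimony", {
  w <- tournament_select(list(make_cand(0.5, 3), make_cand(0.7, 5),
                              make_cand(0.9, 2)))
  expect_equal(w$record$mean_cv_balanced_accuracy, 0.9)
  expect_identical(w$record$complexity, 2)

  w2 <- tournament_select(list(make_cand(0.5, 1), make_cand(0.9, 7),
                               make_cand(0.9, 4)))
  expect_identical(w2$record$complexity, 4)

  # the strictly-lowest-fitness candidate can never win
  set.seed(6)
  for (i in 1:10000) {
    fit <- round(runif(3), 2)
    comp <- sample(1:9, 3, replace = TRUE)
    cands <- Map(make_cand, fit, comp)
    w <- tournament_select(cands)
    if (sum(fit == min(fit)) == 1) {
      expect_gt(w$record$mean_cv_balanced_accuracy, min(fit))
    }
  }
})

test_that("next generation replaces 10% with the elite and keeps the size", {
  fc <- cheap_catalog()
  set.seed(7)
  pop <- lapply(1:10, function(i) random_pipeline(fc, 5))
  recs <- lapply(1:10, function(i) {
    structure(list(mean_cv_balanced_accuracy = i / 10,
                   per_fold_scores = i / 10, complexity = complexity(pop[[i]]),
                   valid = TRUE), class = "fitness_record")
  })
  cfg <- gp_config(population_size = 10, crossover_rate = 0,
                   mutation_rate = 0, seed = 1)
  nxt <- next_generation(pop, recs, cfg, fc)
  expect_length(nxt, 10)
  # one elite copy of the best (fitness 1.0) and closure under zero rates
  expect_identical(serialize_pipeline(nxt[[1]]), serialize_pipeline(pop[[10]]))
  cur <- vapply(pop, serialize_pipeline, "")
  expect_true(all(vapply(nxt, serialize_pipeline, "") %in% cur))

  all_bad <- lapply(recs, function(r) { r$valid <- FALSE; r })
  expect_error(next_generation(pop, all_bad, cfg, fc), "population collapse")
})

test_that("search conserves population size and best fitness is monotone", {
  ds <- separable_dataset(60, seed = 8)
  fc <- cheap_catalog()
  cfg <- gp_config(population_size = 20, max_generations = 6,
                   time_budget = Inf, n_folds = 3, seed = 5,
                   max_operators = 5)
  res <- run_search(ds, fc, cfg)
  expect_identical(nrow(res$history), 7L)
  best_so_far <- cummax(res$history$best)
  expect_identical(res$history$best, best_so_far)
  # archive is mutually non-dominated
  fit <- vapply(res$pareto_archive, function(e) {
    e$record$mean_cv_balanced_accuracy
  }, 0)
  comp <- vapply(res$pareto_archive, function(e) e$record$complexity, 0)
  for (i in seq_along(fit)) {
    dominated <- any(fit >= fit[i] & comp <= comp[i] &
                       (fit > fit[i] | comp < comp[i]))
    expect_false(dominated)
  }
  # best = archive member with maximal fitness, ties to lower complexity
  expect_equal(res$best$record$mean_cv_balanced_accuracy, max(fit))
})

test_that("search is deterministic for a fixed seed", {
  ds <- separable_dataset(40, seed = 9)
  fc <- cheap_catalog()
  cfg <- gp_config(population_size = 12, max_generations = 3,
                   time_budget = Inf, n_folds = 3, seed = 11,
                   max_operators = 4)
  r1 <- run_search(ds, fc, cfg)
  r2 <- run_search(ds, fc, cfg)
  expect_identical(serialize_pipeline(r1$best$tree),
                   serialize_pipeline(r2$best$tree))
  expect_identical(r1$history, r2$history)
})

test_that("representative model takes the best run across seeds", {
  ds <- separable_dataset(40, seed = 10)
  fc <- reduced_configuration("gaussian_nb", n_estimators = 10)
  cfg <- gp_config(population_size = 10, max_generations = 2,
                   time_budget = Inf, n_folds = 3, seed = 30,
                   max_operators = 3)
  rep1 <- representative_model(ds, fc, cfg, n_seeds = 1)
  solo <- run_search(ds, fc, cfg)
  expect_identical(serialize_pipeline(rep1$best$tree),
                   serialize_pipeline(solo$best$tree))

  rep3 <- representative_model(ds, fc, cfg, n_seeds = 3)
  per_seed <- vapply(0:2, function(k) {
    cfgk <- cfg; cfgk$seed <- cfg$seed + k
    run_search(ds, fc, cfgk)$best$record$mean_cv_balanced_accuracy
  }, 0)
  expect_equal(rep3$best$record$mean_cv_balanced_accuracy, max(per_seed))
})
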