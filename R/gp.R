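# Genetic-programming search over pipeline trees: random initialization,
# one-point crossover, operator mutation, elitist replacement (the single
# best pipeline copied into 10% of the next generation, protected from
# variation) and a three-way tournament with two-way parsimony for the
# remaining 90%.

# ---- tree surgery helpers --------------------------------------------------

# paths (integer child-index vectors) to every non-root subtree position
subtree_paths <- function(root) {
  out <- list()
  walk <- function(node, path) {
    for (i in seq_along(node$children %||% list())) {
      out[[length(out) + 1L]] <<- c(path, i)
      walk(node$children[[i]], c(path, i))
    }
  }
  walk(root, integer(0))
  out
}

get_subtree <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

set_subtree <- function(node, path, sub) {
  if (!length(path)) return(sub)
  node$children[[path[1]]] <- set_subtree(node$children[[path[1]]],
                                          path[-1], sub)
  node
}

count_ops <- function(node) {
  own <- as.integer(node$kind %in% c("operator", "classifier"))
  own + sum(vapply(node$children %||% list(), count_ops, integer(1)))
}

# ---- variation operators ---------------------------------------------------

#' One-point crossover of two pipelines
#'
#' Chooses one random compatible point in each parent and exchanges the
#' subtrees below them. Because classifiers live only at the root and cut
#' points are strictly below it, any swap keeps exactly one classifier per
#' offspring; a point pair is compatible when both offspring also respect
#' the complexity cap. If no compatible pair is found the parents are
#' returned unchanged.
#'
#' @param a,b parent [pipeline_tree()]s.
#' @param max_operators complexity cap for the offspring.
#' @return a list of two `pipeline_tree`s with attribute `swapped`.
#' @export
crossover <- function(a, b, max_operators = 10) {
  pa <- subtree_paths(a$root)
  pb <- subtree_paths(b$root)
  for (try in seq_len(20)) {
    cut_a <- draw_one(pa)
    cut_b <- draw_one(pb)
    sub_a <- get_subtree(a$root, cut_a)
    sub_b <- get_subtree(b$root, cut_b)
    new_a <- set_subtree(a$root, cut_a, sub_b)
    new_b <- set_subtree(b$root, cut_b, sub_a)
    if (count_ops(new_a) <= max_operators &&
        count_ops(new_b) <= max_operators) {
      out <- list(pipeline_tree(new_a), pipeline_tree(new_b))
      attr(out, "swapped") <- TRUE
      return(out)
    }
  }
  out <- list(a, b)
  attr(out, "swapped") <- FALSE
  out
}

# parameter slot names of a node (stacking estimator exposes its internal
# estimator choice plus that estimator's own hyperparameters)
param_slots <- function(node, catalog) {
  if (!node$kind %in% c("operator", "classifier")) return(character(0))
  spec <- catalog$specs[[node$name]]
  if (is.null(spec)) return(character(0))
  if (identical(node$name, "stacking_estimator")) {
    return(c("estimator", names(node$params$est_params %||% list())))
  }
  names(spec$hyperparameters)
}

#' Mutate a pipeline
#'
#' Applies one of four moves, chosen uniformly among those applicable:
#' insert a random operator at a random edge, remove a random non-classifier
#' operator, substitute an operator (or, with a multi-classifier catalog,
#' the classifier) by a random same-kind operator, or re-sample one
#' hyperparameter from its domain. Complexity changes by at most one.
#'
#' @param tree a [pipeline_tree()].
#' @param catalog the `operator_catalog` to draw replacements from.
#' @param max_operators complexity cap.
#' @return a valid `pipeline_tree`.
#' @export
mutate_pipeline <- function(tree, catalog, max_operators = 10) {
  root <- tree$root
  paths <- subtree_paths(root)
  node_at <- function(p) get_subtree(root, p)
  op_paths <- Filter(function(p) node_at(p)$kind == "operator", paths)
  kinds <- op_kinds()
  clf_pool <- catalog_classifiers(catalog)

  subst_targets <- Filter(function(p) {
    nd <- node_at(p)
    sum(kinds[catalog_operators(catalog)] == kinds[[nd$name]]) > 1
  }, op_paths)
  can_subst_clf <- length(clf_pool) > 1
  resample_paths <- Filter(function(p) {
    length(param_slots(node_at(p), catalog)) > 0
  }, c(list(integer(0)), paths))

  moves <- c(
    if (count_ops(root) < max_operators) "insert",
    if (length(op_paths)) "remove",
    if (length(subst_targets) || can_subst_clf) "substitute",
    if (length(resample_paths)) "resample"
  )
  if (!length(moves)) return(tree)
  move <- draw_one(moves)

  new_root <- switch(move,
    insert = {
      at <- draw_one(paths)
      nm <- draw_one(catalog_operators(catalog))
      set_subtree(root, at,
                  node_op(nm, sample_spec_params(catalog$specs[[nm]], catalog),
                          get_subtree(root, at)))
    },
    remove = {
      at <- draw_one(op_paths)
      set_subtree(root, at, node_at(at)$children[[1]])
    },
    substitute = {
      targets <- c(subst_targets, if (can_subst_clf) list(integer(0)))
      at <- draw_one(targets)
      nd <- if (length(at)) node_at(at) else root
      pool <- if (nd$kind == "classifier") {
        setdiff(clf_pool, nd$name)
      } else {
        setdiff(catalog_operators(catalog)[
          kinds[catalog_operators(catalog)] == kinds[[nd$name]]], nd$name)
      }
      nm <- draw_one(pool)
      repl <- node_op(nm, sample_spec_params(catalog$specs[[nm]], catalog),
                      nd$children[[1]])
      if (length(at)) set_subtree(root, at, repl) else repl
    },
    resample = {
      at <- draw_one(resample_paths)
      nd <- if (length(at)) node_at(at) else root
      slot <- draw_one(param_slots(nd, catalog))
      if (identical(nd$name, "stacking_estimator")) {
        if (identical(slot, "estimator")) {
          est <- draw_one(catalog$specs$stacking_estimator$hyperparameters$estimator)
          nd$params <- list(estimator = est,
                            est_params = lapply(
                              catalog$specs[[est]]$hyperparameters, draw_one))
        } else {
          est_spec <- catalog$specs[[nd$params$estimator]]
          nd$params$est_params[[slot]] <-
            draw_one(est_spec$hyperparameters[[slot]])
        }
      } else {
        spec <- catalog$specs[[nd$name]]
        nd$params[[slot]] <- draw_one(spec$hyperparameters[[slot]])
      }
      if (length(at)) set_subtree(root, at, nd) else nd
    })
  out <- pipeline_tree(new_root)
  attr(out, "move") <- move
  out
}

# ---- selection -------------------------------------------------------------

rec_fitness <- function(r) {
  if (isTRUE(r$valid)) r$mean_cv_balanced_accuracy else -Inf
}

#' Three-way tournament with two-way parsimony
#'
#' Of three candidate pipelines, the lowest-fitness one is discarded first
#' (fitness ties broken by discarding the more complex); of the remaining
#' two, the less complex wins; a complexity tie goes to the higher fitness,
#' and a full tie is broken uniformly at random.
#'
#' @param candidates list of three `list(tree =, record =)` pairs.
#' @return the winning `list(tree =, record =)`.
#' @export
tournament_select <- function(candidates) {
  stopifnot(length(candidates) == 3)
  fit <- vapply(candidates, function(cand) rec_fitness(cand$record), 0)
  comp <- vapply(candidates, function(cand) cand$record$complexity, 0)
  lowest <- which(fit == min(fit))
  drop <- if (length(lowest) > 1) lowest[which.max(comp[lowest])] else lowest
  rest <- setdiff(1:3, drop)
  c1 <- rest[1]; c2 <- rest[2]
  win <- if (comp[c1] != comp[c2]) {
    rest[which.min(comp[rest])]
  } else if (fit[c1] != fit[c2]) {
    rest[which.max(fit[rest])]
  } else {
    rest[sample.int(2, 1)]
  }
  candidates[[win]]
}

# ---- generation step -------------------------------------------------------

#' Genetic-programming configuration
#'
#' @param population_size pipelines per generation (>= 10).
#' @param max_generations generation budget.
#' @param time_budget wall-clock budget in seconds (checked between
#'   generations; `Inf` disables it).
#' @param crossover_rate,mutation_rate fraction of the new population
#'   subjected to one-point crossover / mutation.
#' @param n_folds cross-validation folds for fitness.
#' @param seed master seed; every source of randomness derives from it.
#' @param max_operators pipeline complexity cap.
#' @param refold_per_generation redraw CV folds each generation (default
#'   `FALSE`: folds are fixed for the whole run, which makes best-so-far
#'   fitness monotone under elitism).
#' @param stop_at_perfect end the run once a pipeline reaches fitness 1.0
#'   (off by default). Balanced accuracy is bounded by 1, so stopping there
#'   cannot change the best result, only save generations.
#' @return a list of class `gp_config`.
#' @export
gp_config <- function(population_size = 1000, max_generations = 1000,
                      time_budget = 24 * 3600, crossover_rate = 0.1,
                      mutation_rate = 0.9, n_folds = 10, seed = 42,
                      max_operators = 10, refold_per_generation = FALSE,
                      stop_at_perfect = FALSE) {
  if (population_size < 10) stop("population_size must be >= 10")
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 time_budget = time_budget,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_fraction = 0.10, tournament_size = 3L,
                 n_folds = n_folds, seed = seed,
                 max_operators = max_operators,
                 refold_per_generation = refold_per_generation,
                 stop_at_perfect = stop_at_perfect),
            class = "gp_config")
}

#' Produce the next generation
#'
#' The single highest-fitness pipeline replaces 10% of the population
#' (elite copies, protected from variation); the remaining 90% are filled
#' with three-way-tournament winners; crossover and mutation are then
#' applied to the configured fractions of the non-elite slots.
#'
#' @param population list of `pipeline_tree`s.
#' @param records aligned list of `fitness_record`s.
#' @param config a [gp_config()].
#' @param catalog the `operator_catalog` mutations draw from.
#' @return a list of `pipeline_tree`s of the same size.
#' @export
next_generation <- function(population, records, config,
                            catalog = attr(config, "catalog") %||%
                              full_configuration()) {
  n <- length(population)
  stopifnot(length(records) == n)
  fit <- vapply(records, rec_fitness, 0)
  if (all(fit == -Inf)) stop("population collapse: all pipelines invalid")
  comp <- vapply(records, function(r) r$complexity, 0)
  n_elite <- max(1L, round_half_up(config$elite_fraction * n))
  best <- order(-fit, comp)[1]

  new_pop <- vector("list", n)
  for (i in seq_len(n_elite)) new_pop[[i]] <- population[[best]]
  for (i in seq(n_elite + 1, n)) {
    triple <- sample.int(n, 3, replace = TRUE)
    new_pop[[i]] <- tournament_select(lapply(triple, function(j) {
      list(tree = population[[j]], record = records[[j]])
    }))$tree
  }

  non_elite <- seq(n_elite + 1, n)
  n_cx <- min(2 * floor(config$crossover_rate * n / 2), length(non_elite))
  if (n_cx >= 2) {
    slots <- sample(non_elite, n_cx)
    for (k in seq(1, n_cx, by = 2)) {
      off <- crossover(new_pop[[slots[k]]], new_pop[[slots[k + 1]]],
                       config$max_operators)
      new_pop[[slots[k]]] <- off[[1]]
      new_pop[[slots[k + 1]]] <- off[[2]]
    }
  }
  n_mut <- min(round_half_up(config$mutation_rate * n), length(non_elite))
  if (n_mut > 0) {
    mslots <- sample(non_elite, n_mut)
    for (i in mslots) {
      new_pop[[i]] <- mutate_pipeline(new_pop[[i]], catalog, config$max_operators)
    }
  }
  new_pop
}

# ---- full search -----------------------------------------------------------

pareto_filter <- function(entries) {
  if (!length(entries)) return(entries)
  fit <- vapply(entries, function(e) rec_fitness(e$record), 0)
  comp <- vapply(entries, function(e) e$record$complexity, 0)
  keep <- vapply(seq_along(entries), function(i) {
    !any(fit >= fit[i] & comp <= comp[i] & (fit > fit[i] | comp < comp[i]))
  }, logical(1))
  entries[keep]
}

#' Run the genetic-programming pipeline search
#'
#' Initializes a random population, then loops evaluate -> next generation
#' until the generation or time budget is exhausted, maintaining a Pareto
#' archive of pipelines non-dominated in (cross-validated balanced accuracy,
#' complexity). Deterministic for a fixed seed when no time budget binds.
#'
#' @param data an imputed, binary [labeled_dataset()] with both class counts
#'   `>= n_folds`.
#' @param catalog an `operator_catalog`.
#' @param config a [gp_config()].
#' @return an object of class `search_result` with elements `best`
#'   (`list(tree, record)`), `pareto_archive`, `history` (per-generation
#'   best/mean fitness data frame) and `seed`.
#' @export
run_search <- function(data, catalog, config = gp_config()) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (anyNA(data$table$values)) stop("impute the data before searching")
  attr(config, "catalog") <- catalog
  t_start <- Sys.time()
  cache <- new.env(parent = emptyenv())
  eval_seed_for <- function(gen) {
    if (config$refold_per_generation) derive_seed(config$seed, 1009L, gen)
    else derive_seed(config$seed, 1009L)
  }
  evaluate_all <- function(pop, gen) {
    es <- eval_seed_for(gen)
    lapply(pop, function(tree) {
      key <- paste0(es, "|", serialize_pipeline(tree))
      if (!is.null(cache[[key]])) return(cache[[key]])
      rec <- evaluate_cv(tree, data, config$n_folds, seed = es)
      cache[[key]] <- rec
      rec
    })
  }

  archive <- list()
  evaluations <- list() # every (tree, record) pair ever evaluated
  history <- data.frame(generation = integer(), best = double(),
                        mean = double())
  update_archive <- function(pop, recs) {
    valid <- which(vapply(recs, function(r) isTRUE(r$valid), logical(1)))
    entries <- lapply(valid, function(i) list(tree = pop[[i]],
                                              record = recs[[i]]))
    evaluations <<- c(evaluations, entries)
    merged <- c(archive, entries)
    merged <- merged[!duplicated(vapply(merged, function(e) {
      serialize_pipeline(e$tree)
    }, character(1)))]
    archive <<- pareto_filter(merged)
  }
  log_gen <- function(gen, recs) {
    fit <- vapply(recs, rec_fitness, 0)
    ok <- is.finite(fit)
    history[nrow(history) + 1L, ] <<- list(gen, max(fit[ok], -Inf),
                                           mean(fit[ok]))
  }

  population <- with_seed(derive_seed(config$seed, 2027L), {
    lapply(seq_len(config$population_size), function(i) {
      random_pipeline(catalog, config$max_operators)
    })
  })
  records <- evaluate_all(population, 0L)
  update_archive(population, records)
  log_gen(0L, records)

  for (gen in seq_len(config$max_generations)) {
    if (as.numeric(difftime(Sys.time(), t_start, units = "secs")) >
        config$time_budget) break
    if (isTRUE(config$stop_at_perfect) &&
        max(vapply(records, rec_fitness, 0)) >= 1) break
    population <- with_seed(derive_seed(config$seed, 3037L, gen), {
      next_generation(population, records, config)
    })
    records <- evaluate_all(population, gen)
    update_archive(population, records)
    log_gen(gen, records)
  }

  if (!length(archive)) stop("population collapse: no valid pipeline found")
  fit <- vapply(archive, function(e) rec_fitness(e$record), 0)
  comp <- vapply(archive, function(e) e$record$complexity, 0)
  best <- archive[[order(-fit, comp)[1]]]
  structure(list(best = best, pareto_archive = archive, history = history,
                 evaluations = evaluations, seed = config$seed,
                 config = config),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> best CV bal_acc=%.4f complexity=%d (archive size %d)\n  %s\n",
    x$best$record$mean_cv_balanced_accuracy, x$best$record$complexity,
    length(x$pareto_archive), serialize_pipeline(x$best$tree)))
  invisible(x)
}

#' Multi-seed representative-model protocol
#'
#' Runs [run_search()] with seeds `seed + 0 ... seed + n_seeds - 1` and
#' returns the run whose best pipeline attains the maximal cross-validated
#' balanced accuracy (ties broken by smaller complexity, then smaller seed),
#' compensating for initialization effects of the stochastic search.
#'
#' @inheritParams run_search
#' @param n_seeds number of independent runs.
#' @return the winning `search_result`.
#' @export
representative_model <- function(data, catalog, config = gp_config(),
                                 n_seeds = 50) {
  stopifnot(n_seeds >= 1)
  runs <- lapply(seq_len(n_seeds) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    run_search(data, catalog, cfg)
  })
  fit <- vapply(runs, function(r) rec_fitness(r$best$record), 0)
  comp <- vapply(runs, function(r) r$best$record$complexity, 0)
  seeds <- vapply(runs, function(r) r$seed, 0)
  runs[[order(-fit, comp, seeds)[1]]]
}
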