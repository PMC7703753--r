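#' Synthetic cohort configuration
#'
#' Parameters of the synthetic generator that emulates the *shape* of an
#' angiography cohort with NMR-derived metabolic measures: ~925 samples, 73
#' correlated continuous "metabolic" features, 27 mixed "clinical" features,
#' a three-level latent disease severity (none / non-obstructive /
#' obstructive) binarized two ways, class imbalance and missingness. It does
#' not attempt to match any real covariance structure, units or feature
#' names; the class proportions and missingness rate are assumptions, not
#' published cohort values.
#'
#' @param n_samples number of samples (default 925).
#' @param n_metabolic continuous block-correlated features (default 73);
#'   half of them are exponentiated to a positive, skewed scale.
#' @param n_clinical mixed binary/continuous features (default 27).
#' @param class_proportions length-3 vector over severities (0, 1, 2);
#'   must sum to 1 with no empty class.
#' @param n_informative_metabolic,n_informative_clinical planted signal
#'   counts.
#' @param effect_size mean shift per severity level on informative metabolic
#'   columns, and the per-level logit shift of informative clinical rates.
#' @param correlation_block_size size of the metabolic correlation blocks
#'   (within-block correlation 0.6).
#' @param xor_pair add two binary features whose XOR shifts the severity
#'   logit, so linear models underfit while interaction-capable pipelines do
#'   not.
#' @param missing_rate MCAR missingness applied to metabolic columns only.
#' @param seed integer seed; generation is fully deterministic in it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 925, n_metabolic = 73,
                             n_clinical = 27,
                             class_proportions = c(0.20, 0.20, 0.60),
                             n_informative_metabolic = 10,
                             n_informative_clinical = 5,
                             effect_size = 1.0,
                             correlation_block_size = 5,
                             xor_pair = FALSE,
                             missing_rate = 0.05,
                             seed = 1) {
  if (length(class_proportions) != 3 ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must be a 3-vector summing to 1")
  }
  if (any(class_proportions <= 0)) {
    stop("degenerate class proportions: every severity level needs mass")
  }
  if (n_informative_metabolic > n_metabolic ||
      n_informative_clinical > n_clinical) {
    stop("informative counts cannot exceed feature counts")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a three-level latent severity from the configured proportions
#' (exact counts up to rounding when no XOR pair is planted), then builds:
#' metabolic features as block-correlated Gaussians (within-block
#' correlation 0.6) whose informative columns get a mean shift of
#' `effect_size * severity`, with the second half of the columns
#' exponentiated to a positive skewed scale; clinical features as a mix of
#' severity-dependent Bernoulli indicators (informative), noise Bernoulli
#' and noise Gaussian columns. Labels: profile P1 = severity >= 1, profile
#' P2 = severity = 2. MCAR missingness is applied to metabolic columns only.
#'
#' @param config a [synthetic_config()].
#' @return a list with `p1` and `p2` ([labeled_dataset()]s over the same
#'   feature table) and `truth` (a `synthetic_ground_truth` with the latent
#'   classes, informative indices/names, effect sizes and XOR pair indices).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, 929L), {
    n <- cfg$n_samples
    # xor pair occupies the last two clinical slots when requested
    xor_cols <- NULL
    xor_vals <- NULL
    if (cfg$xor_pair) {
      xor_vals <- cbind(stats::rbinom(n, 1, 0.5), stats::rbinom(n, 1, 0.5))
    }

    # latent severity: exact per-class counts when independent of features,
    # proportional-odds sampling shifted by the XOR signal otherwise
    severity <- if (cfg$xor_pair) {
      theta <- stats::qlogis(cumsum(cfg$class_proportions))[1:2]
      eta <- 2 * cfg$effect_size * as.numeric(xor(xor_vals[, 1] == 1,
                                                  xor_vals[, 2] == 1))
      latent <- eta + stats::rlogis(n)
      as.integer(latent > theta[1]) + as.integer(latent > theta[2])
    } else {
      counts <- round_half_up(cfg$class_proportions * n)
      counts[3] <- n - counts[1] - counts[2]
      sample(rep.int(0:2, counts))
    }

    # metabolic block: z = sqrt(rho) u_block + sqrt(1-rho) eps
    rho <- 0.6
    B <- max(1L, cfg$correlation_block_size)
    block_of <- ((seq_len(cfg$n_metabolic) - 1L) %/% B) + 1L
    u <- matrix(stats::rnorm(n * max(block_of)), n, max(block_of))
    met <- sqrt(rho) * u[, block_of, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * cfg$n_metabolic), n,
                             cfg$n_metabolic)
    inf_met <- seq_len(cfg$n_informative_metabolic)
    eff_met <- rep(cfg$effect_size, length(inf_met))
    for (j in seq_along(inf_met)) {
      met[, inf_met[j]] <- met[, inf_met[j]] + eff_met[j] * severity
    }
    skewed <- seq_len(cfg$n_metabolic) > cfg$n_metabolic / 2
    met[, skewed] <- exp(met[, skewed] / 2)

    # clinical block: informative Bernoulli, then noise Bernoulli/Gaussian
    n_noise <- cfg$n_clinical - cfg$n_informative_clinical -
      if (cfg$xor_pair) 2L else 0L
    if (n_noise < 0) stop("n_clinical too small for informative + xor columns")
    inf_clin_p <- stats::plogis(cfg$effect_size * (severity - 1))
    clin_inf <- matrix(stats::rbinom(n * cfg$n_informative_clinical, 1,
                                     rep(inf_clin_p,
                                         cfg$n_informative_clinical)),
                       n, cfg$n_informative_clinical)
    n_noise_bin <- ceiling(n_noise / 2)
    noise_rates <- stats::runif(n_noise_bin, 0.1, 0.9)
    clin_noise_bin <- vapply(seq_len(n_noise_bin), function(j) {
      stats::rbinom(n, 1, noise_rates[j])
    }, numeric(n))
    clin_noise_cont <- matrix(stats::rnorm(n * (n_noise - n_noise_bin)), n,
                              n_noise - n_noise_bin)
    clin <- cbind(clin_inf, clin_noise_bin, clin_noise_cont, xor_vals)

    values <- cbind(met, clin)
    met_names <- sprintf("met%02d", seq_len(cfg$n_metabolic))
    clin_names <- sprintf("clin%02d", seq_len(cfg$n_clinical))
    colnames(values) <- c(met_names, clin_names)
    kinds <- c(rep("continuous", cfg$n_metabolic),
               rep("binary", cfg$n_informative_clinical),
               rep("binary", n_noise_bin),
               rep("continuous", n_noise - n_noise_bin),
               rep("binary", if (cfg$xor_pair) 2L else 0L))

    # MCAR missingness on metabolic columns only
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(n * cfg$n_metabolic) < cfg$missing_rate,
                     n, cfg$n_metabolic)
      # never blank out a full sample's metabolic block
      full_rows <- rowSums(mask) == cfg$n_metabolic
      mask[full_rows, 1] <- FALSE
      values[, seq_len(cfg$n_metabolic)][mask] <- NA_real_
    }

    tab <- feature_table(values, feature_kinds = kinds,
                         sample_ids = sprintf("s%04d", seq_len(n)))
    inf_idx <- c(inf_met, cfg$n_metabolic + seq_len(cfg$n_informative_clinical))
    xor_idx <- if (cfg$xor_pair) {
      cfg$n_metabolic + cfg$n_clinical - c(1L, 0L)
    }
    truth <- structure(list(
      latent_class = severity,
      informative_idx = inf_idx,
      informative_names = colnames(values)[inf_idx],
      effect_sizes = c(eff_met, rep(cfg$effect_size,
                                    cfg$n_informative_clinical)),
      xor_idx = xor_idx,
      xor_names = if (!is.null(xor_idx)) colnames(values)[xor_idx]),
      class = "synthetic_ground_truth")

    list(p1 = labeled_dataset(tab, as.integer(severity >= 1), "P1"),
         p2 = labeled_dataset(tab, as.integer(severity == 2), "P2"),
         truth = truth)
  })
}

#' Generate an XOR-structured dataset
#'
#' Two balanced binary features whose exclusive-or defines the label, plus
#' independent Gaussian noise features. Logistic regression cannot express
#' the XOR decision rule, while tree classifiers and interaction-building
#' constructors can, which is the mechanism motivating pipeline search over
#' bare model tuning.
#'
#' @param n samples (default 400).
#' @param n_noise Gaussian noise features (default 8).
#' @param seed integer seed.
#' @return a [labeled_dataset()]; the two signal columns are `b1` and `b2`.
#' @export
generate_xor_dataset <- function(n = 400, n_noise = 8, seed = 1) {
  with_seed(derive_seed(seed, 4242L), {
    b1 <- stats::rbinom(n, 1, 0.5)
    b2 <- stats::rbinom(n, 1, 0.5)
    noise <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    values <- cbind(b1, b2, noise)
    colnames(values) <- c("b1", "b2", sprintf("noise%d", seq_len(n_noise)))
    tab <- feature_table(values,
                         feature_kinds = c("binary", "binary",
                                           rep("continuous", n_noise)),
                         sample_ids = sprintf("s%04d", seq_len(n)))
    labeled_dataset(tab, as.integer(xor(b1 == 1, b2 == 1)), "other")
  })
}
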