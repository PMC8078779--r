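# synthetic_data: paired mutation/expression cohorts with planted stage signal.

#' Configuration for the synthetic cohort simulator
#'
#' Defines a four-stage cohort in which a subset of "informative" genes carries
#' both an ordinal expression signal (stage-s mean `s * effect_size`, in units
#' of the within-stage standard deviation) and a mutation-frequency gradient
#' (stage-s mutation probability `min(1, mut_baseline * mut_gradient^(s-1))`).
#' All other genes are stage-independent noise. Setting `effect_size = 0` and
#' `mut_gradient = 1` produces a global null cohort.
#'
#' @param stage_counts integer vector of length 4, samples per stage
#'   (default balanced 60/60/60/60; `c(12, 24, 29, 12)` mirrors a severely
#'   imbalanced rectal-cancer cohort).
#' @param n_genes total number of genes (default 200).
#' @param n_informative number of genes carrying stage signal (default 10).
#' @param effect_size per-stage expression mean shift in within-stage SD units
#'   (default 1.0).
#' @param mut_baseline baseline mutation frequency q0 (default 0.05).
#' @param mut_gradient multiplicative per-stage mutation-frequency gradient for
#'   informative genes (default 2.5; 1 means no mutation signal).
#' @param noise_sd within-stage expression standard deviation (default 1.0).
#' @param n_batches number of batches (default 1 = no batch structure).
#' @param batch_shift additive expression shift of batch b relative to batch 1,
#'   `(b-1) * batch_shift` (default 0).
#' @param decoupled if `TRUE`, the mutation signal is planted in a disjoint
#'   gene set from the expression signal, modelling failure of the premise that
#'   mutation-selected genes carry stage-relevant expression.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(stage_counts = c(60, 60, 60, 60),
                             n_genes = 200, n_informative = 10,
                             effect_size = 1.0, mut_baseline = 0.05,
                             mut_gradient = 2.5, noise_sd = 1.0,
                             n_batches = 1, batch_shift = 0,
                             decoupled = FALSE, seed = 1) {
  assert_that(length(stage_counts) == 4 && all(stage_counts >= 2),
              "stage_counts must give >= 2 samples for each of 4 stages")
  needed <- if (decoupled) 2 * n_informative else n_informative
  assert_that(needed <= n_genes, "n_informative exceeds n_genes")
  assert_that(mut_baseline >= 0 && mut_baseline <= 1,
              "mut_baseline must be a probability")
  assert_that(noise_sd >= 0 && effect_size >= 0 && mut_gradient >= 0,
              "effect_size, mut_gradient and noise_sd must be non-negative")
  structure(list(stage_counts = as.integer(stage_counts), n_genes = n_genes,
                 n_informative = n_informative, effect_size = effect_size,
                 mut_baseline = mut_baseline, mut_gradient = mut_gradient,
                 noise_sd = noise_sd, n_batches = n_batches,
                 batch_shift = batch_shift, decoupled = decoupled, seed = seed),
            class = "synthetic_config")
}

#' Simulate a paired mutation/expression cohort with planted stage structure
#'
#' @param config a [synthetic_config()].
#' @return list with elements `cohort` (a [cohort_dataset()]) and `truth`
#'   (informative gene ids for expression and mutation, per-stage true means,
#'   batch assignments).
#' @examples
#' syn <- make_synthetic_cohort(synthetic_config(seed = 7))
#' syn$truth$informative_genes
#' @export
make_synthetic_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- sum(config$stage_counts)
    stages <- rep(1:4, times = config$stage_counts)
    ids <- sprintf("S%04d", seq_len(n))
    genes <- sprintf("g%04d", seq_len(config$n_genes))

    pick <- sample(config$n_genes,
                   if (config$decoupled) 2 * config$n_informative
                   else config$n_informative)
    expr_inf <- sort(pick[seq_len(config$n_informative)])
    mut_inf <- if (config$decoupled) {
      sort(pick[config$n_informative + seq_len(config$n_informative)])
    } else expr_inf

    expr <- matrix(stats::rnorm(n * config$n_genes, 0, config$noise_sd),
                   n, config$n_genes, dimnames = list(ids, genes))
    for (g in expr_inf) {
      expr[, g] <- expr[, g] + stages * config$effect_size
    }

    q_noise <- config$mut_baseline
    mut <- matrix(stats::rbinom(n * config$n_genes, 1, q_noise),
                  n, config$n_genes, dimnames = list(ids, genes))
    for (g in mut_inf) {
      q <- pmin(1, config$mut_baseline * config$mut_gradient^(stages - 1))
      mut[, g] <- stats::rbinom(n, 1, q)
    }

    batch <- NULL
    if (config$n_batches > 1) {
      batch <- sample(rep_len(seq_len(config$n_batches), n))
      expr <- expr + (batch - 1) * config$batch_shift
      batch <- paste0("B", batch)
    }

    list(
      cohort = cohort_dataset(expr, mut, stages, ids, batch),
      truth = list(
        informative_genes = genes[expr_inf],
        informative_mut_genes = genes[mut_inf],
        stage_means = (1:4) * config$effect_size,
        batch = batch,
        config = config
      )
    )
  })
}
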