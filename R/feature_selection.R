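# feature_selection: mutation-based random-forest gene ranking with
# permutation p-values.

#' Feature-selection configuration
#'
#' @param p_threshold permutation p-value gate for [select_features()]
#'   (default 0.004; genes pass with p strictly below it).
#' @param n_trees trees per forest (default 100, the classifier RF setting).
#' @param n_permutations label permutations used for the null importance
#'   distribution (default 1000). Must be at least 100 when
#'   `p_threshold <= 0.01` so the p-value resolution `1/(n_permutations+1)`
#'   supports the gate.
#' @param seed integer seed; permutation replicate b refits the forest with
#'   seed `seed + b`.
#' @return a `fs_config` list.
#' @export
fs_config <- function(p_threshold = 0.004, n_trees = 100,
                      n_permutations = 1000, seed = 1) {
  assert_that(p_threshold > 0 && p_threshold <= 1,
              "p_threshold must be in (0, 1]")
  assert_that(is_count(n_trees), "n_trees must be a positive integer")
  assert_that(is_count(n_permutations),
              "n_permutations must be a positive integer")
  if (p_threshold <= 0.01 && n_permutations < 100) {
    stop("n_permutations must be >= 100 when p_threshold <= 0.01 ",
         "(p-value resolution must support the threshold)", call. = FALSE)
  }
  structure(list(p_threshold = p_threshold, n_trees = n_trees,
                 n_permutations = n_permutations, seed = seed),
            class = "fs_config")
}

# One forest fit returning raw impurity (Gini) importance per gene.
rf_importance <- function(mutation, stages, n_trees, seed) {
  fit <- ranger::ranger(x = mutation, y = factor(stages),
                        num.trees = n_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  imp[colnames(mutation)]
}

check_fs_inputs <- function(mutation, stages) {
  assert_that(all(mutation %in% c(0, 1)), "mutation matrix must be binary 0/1")
  assert_that(length(unique(stages)) >= 2,
              "stage vector is constant; ranking needs >= 2 distinct stages")
}

#' Rank genes by random-forest importance on the mutation matrix
#'
#' Fits a random forest predicting stage from the binary mutation profiles and
#' returns the impurity (Gini) importance of every gene, normalised to sum
#' to 1. Deterministic given `config$seed`.
#'
#' @param mutation binary matrix, samples x genes, column names = gene ids.
#' @param stages integer stage labels (1-4), one per row.
#' @param config a [fs_config()].
#' @return An object of class `feature_ranking`: data frame with columns
#'   `gene_id`, `importance` and (after [permutation_pvalues()]) `p_value`,
#'   sorted by decreasing importance.
#' @export
rank_features_rf <- function(mutation, stages, config = fs_config()) {
  check_fs_inputs(mutation, stages)
  raw <- rf_importance(mutation, stages, config$n_trees, config$seed)
  imp <- if (sum(raw) > 0) raw / sum(raw) else raw
  out <- data.frame(gene_id = colnames(mutation), importance = unname(imp),
                    p_value = NA_real_, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "raw_importance") <- raw
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Permutation p-values for random-forest gene importance
#'
#' For each gene g the p-value is the add-one tail estimate
#' `(1 + #\{b : importance_b(g) >= importance_obs(g)\}) / (1 + B)`, where
#' replicate b refits the forest after permuting the stage labels. Ties count
#' as exceedances, so p-values live in (0, 1] and are exactly 1 for genes with
#' zero observed importance.
#'
#' @inheritParams rank_features_rf
#' @return a `feature_ranking` data frame with `p_value` filled in.
#' @export
permutation_pvalues <- function(mutation, stages, config = fs_config()) {
  ranking <- rank_features_rf(mutation, stages, config)
  obs <- attr(ranking, "raw_importance")
  exceed <- stats::setNames(numeric(length(obs)), names(obs))
  perms <- with_seed(derive_seed(config$seed, 104729), {
    replicate(config$n_permutations, sample(stages), simplify = FALSE)
  })
  for (b in seq_len(config$n_permutations)) {
    null_imp <- rf_importance(mutation, perms[[b]], config$n_trees,
                              config$seed + b)
    exceed <- exceed + (null_imp >= obs)
  }
  p <- (1 + exceed) / (1 + config$n_permutations)
  ranking$p_value <- unname(p[ranking$gene_id])
  ranking
}

#' Select genes passing the permutation p-value gate
#'
#' @param ranking a `feature_ranking` from [permutation_pvalues()].
#' @param p_threshold significance gate; genes with `p_value < p_threshold`
#'   (strictly) are kept.
#' @return character vector of gene ids, ordered by decreasing importance.
#' @export
select_features <- function(ranking, p_threshold = 0.004) {
  assert_that(p_threshold > 0 && p_threshold <= 1,
              "p_threshold must be in (0, 1]")
  assert_that(!anyNA(ranking$p_value),
              "p-values missing; run permutation_pvalues() first")
  ranking$gene_id[ranking$p_value < p_threshold]
}
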