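# evaluation: repeated-split experiment harness, t-tests, PCA diagnostics,
# subsample experiment and augmentation-fold sweep.

ALL_VARIANTS <- c("Ori", "FS", "MS", "SMOTE", "DA",
                  "GAN1", "GAN5", "GAN20", "GAN100")
ALL_CLASSIFIERS <- c("1DCNN", "DNN", "RF")

#' Experiment configuration
#'
#' @param variants dataset variants to run: subset of `"Ori"` (all genes, no
#'   augmentation), `"FS"` (selected genes), `"MS"`, `"SMOTE"`, `"DA"` and
#'   `"GANk"` for any integer fold k (e.g. `"GAN5"`).
#' @param classifiers subset of `"1DCNN"`, `"DNN"`, `"RF"`.
#' @param repeats number of independent 70/30 cycles (default 10).
#' @param base_seed integer; repeat r uses a split seed derived from
#'   `(base_seed, r)` so controlled comparisons share splits.
#' @param train_fraction training fraction per split (default 0.7).
#' @param fs a [fs_config()] used for gene selection.
#' @param gan a [gan_config()] template for the GAN variants.
#' @param cnn,dnn,rf classifier configuration templates.
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @param da_epochs denoising-autoencoder training epochs (default 100).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(variants = ALL_VARIANTS,
                              classifiers = ALL_CLASSIFIERS,
                              repeats = 10, base_seed = 1,
                              train_fraction = 0.7,
                              fs = fs_config(), gan = gan_config(),
                              cnn = cnn_config(), dnn = dnn_config(),
                              rf = rf_config(), smote_k = 5,
                              da_epochs = 100) {
  assert_that(length(variants) >= 1, "variant set must be non-empty")
  bad <- variants[!(variants %in% ALL_VARIANTS |
                      grepl("^GAN[0-9]+$", variants))]
  assert_that(length(bad) == 0,
              paste("unknown variant(s):", paste(bad, collapse = ", ")))
  assert_that(all(classifiers %in% ALL_CLASSIFIERS),
              "classifiers must be among 1DCNN, DNN, RF")
  assert_that(is_count(repeats), "repeats must be >= 1")
  structure(list(variants = variants, classifiers = classifiers,
                 repeats = repeats, base_seed = base_seed,
                 train_fraction = train_fraction, fs = fs, gan = gan,
                 cnn = cnn, dnn = dnn, rf = rf, smote_k = smote_k,
                 da_epochs = da_epochs),
            class = "experiment_config")
}

variant_fold <- function(v) {
  if (grepl("^GAN[0-9]+$", v)) as.integer(sub("^GAN", "", v)) else NA_integer_
}

# Training set for one variant. split_all carries all genes, split_sel the
# selected genes; vseed drives the augmenter's randomness.
variant_training_set <- function(split_all, split_sel, variant, config, vseed) {
  fold <- variant_fold(variant)
  if (!is.na(fold)) {
    gcfg <- config$gan
    gcfg$seed <- vseed
    return(augment_gan(split_sel, fold, gcfg))
  }
  switch(variant,
         Ori = list(expression = split_all$train$expression,
                    stages = split_all$train$stages),
         FS = list(expression = split_sel$train$expression,
                   stages = split_sel$train$stages),
         MS = augment_ms(split_sel, seed = vseed),
         SMOTE = augment_smote(split_sel, config$smote_k, seed = vseed),
         DA = augment_da(split_sel, seed = vseed, epochs = config$da_epochs),
         stop("unknown variant: ", variant))
}

classifier_template <- function(config, kind) {
  switch(kind, "1DCNN" = config$cnn, "DNN" = config$dnn, "RF" = config$rf)
}

# One (variant x classifier) cell on a given split. Returns accuracy/macro_f1
# or NA plus the error message.
run_cell <- function(split_all, split_sel, variant, kind, config, r) {
  fold <- variant_fold(variant)
  vseed <- derive_seed(config$base_seed, r,
                       match(variant, ALL_VARIANTS, nomatch = 99L),
                       if (is.na(fold)) 0L else fold)
  tryCatch({
    train_set <- variant_training_set(split_all, split_sel, variant, config,
                                      vseed)
    ccfg <- classifier_template(config, kind)
    if (kind != "RF") {  # RF keeps its pinned random_state; nets vary by cell
      ccfg$seed <- derive_seed(vseed, match(kind, ALL_CLASSIFIERS))
    }
    test <- if (variant == "Ori") split_all$test else split_sel$test
    # hygiene: augmenters and classifiers only ever see training rows
    stopifnot(length(intersect(rownames(train_set$expression),
                               test$sample_ids)) == 0)
    model <- train_classifier(train_set, ccfg)
    res <- evaluate_classifier(model, test)
    list(accuracy = res$accuracy, macro_f1 = res$macro_f1, error = NA_character_)
  }, error = function(e) {
    list(accuracy = NA_real_, macro_f1 = NA_real_,
         error = conditionMessage(e))
  })
}

select_or_use <- function(cohort, config, selected_genes) {
  if (!is.null(selected_genes)) return(selected_genes)
  ranking <- permutation_pvalues(cohort$mutation, cohort$stages, config$fs)
  sel <- select_features(ranking, config$fs$p_threshold)
  if (length(sel) == 0) {
    stop("gene selection returned no genes at p < ",
         config$fs$p_threshold, call. = FALSE)
  }
  sel
}

#' Run the repeated-split augmentation experiment
#'
#' One cycle per repeat: a fresh stratified 70/30 split, variant-specific
#' training sets built from the training side only, one classifier fit per
#' (variant, classifier) cell, evaluation on the untouched 30%. All variants
#' share the split within a repeat, so comparisons are controlled. Gene
#' selection (needed by every variant except `Ori`) is computed once from the
#' cohort's mutation matrix, or supplied via `selected_genes`.
#'
#' @param cohort a [cohort_dataset()].
#' @param config an [experiment_config()].
#' @param selected_genes optional precomputed gene selection (character).
#' @return a `results_table` data frame with columns `variant`, `classifier`,
#'   `repeat`, `accuracy`, `macro_f1`, `error`; the gene selection used is
#'   attached as attribute `"selected_genes"`. Failed cells carry `NA` metrics
#'   and the error message.
#' @export
run_experiment <- function(cohort, config = experiment_config(),
                           selected_genes = NULL) {
  need_sel <- any(config$variants != "Ori")
  sel <- if (need_sel) select_or_use(cohort, config, selected_genes)
         else character(0)
  rows <- list()
  for (r in seq_len(config$repeats)) {
    split_all <- stratified_split(cohort, config$train_fraction,
                                  seed = derive_seed(config$base_seed, r))
    split_sel <- if (need_sel) restrict_genes(split_all, sel) else split_all
    for (v in config$variants) {
      for (k in config$classifiers) {
        cell <- run_cell(split_all, split_sel, v, k, config, r)
        rows[[length(rows) + 1]] <- data.frame(
          variant = v, classifier = k, accuracy = cell$accuracy,
          macro_f1 = cell$macro_f1, error = cell$error,
          stringsAsFactors = FALSE, check.names = FALSE)
        rows[[length(rows)]][["repeat"]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("variant", "classifier", "repeat", "accuracy", "macro_f1",
                 "error")]
  attr(out, "selected_genes") <- sel
  class(out) <- c("results_table", "data.frame")
  out
}

#' Aggregate a results table to mean and standard deviation
#'
#' @param results a results table from [run_experiment()],
#'   [subsample_experiment()] or [fold_sweep()].
#' @return data frame with one row per grouping cell and columns
#'   `accuracy_mean`, `accuracy_sd`, `macro_f1_mean`, `macro_f1_sd`, `n`.
#' @export
summarize_results <- function(results) {
  by_cols <- intersect(c("variant", "classifier", "fraction", "arm", "fold"),
                       names(results))
  groups <- results[by_cols]
  agg <- function(col, f) {
    stats::aggregate(results[[col]], groups,
                     function(v) f(v[!is.na(v)]))$x
  }
  base <- stats::aggregate(results$accuracy, groups,
                           function(v) sum(!is.na(v)))
  out <- base[by_cols]
  out$n <- base$x
  out$accuracy_mean <- agg("accuracy", mean)
  out$accuracy_sd <- agg("accuracy", stats::sd)
  out$macro_f1_mean <- agg("macro_f1", mean)
  out$macro_f1_sd <- agg("macro_f1", stats::sd)
  out
}

#' Welch two-sample t-test between per-repeat metric vectors
#'
#' @param results_a,results_b numeric vectors (at least 2 values each) of a
#'   metric across repeats.
#' @return the Welch t-test p-value in (0, 1]. Two constant vectors with equal
#'   means return 1; constant vectors with different means return the smallest
#'   positive double.
#' @export
compare_ttest <- function(results_a, results_b) {
  assert_that(length(results_a) >= 2 && length(results_b) >= 2,
              "need >= 2 values per group")
  if (stats::sd(results_a) == 0 && stats::sd(results_b) == 0) {
    return(if (mean(results_a) == mean(results_b)) 1.0
           else .Machine$double.xmin)
  }
  stats::t.test(results_a, results_b, var.equal = FALSE)$p.value
}

#' PCA diagnostics for original versus generated samples
#'
#' Fits principal components on the pooled (original + generated) samples and
#' returns 2-D sample coordinates, plus a gene-level view in which each gene
#' of each dataset is a point (the two datasets are row-subsampled to a common
#' sample count when they differ, so gene profiles are comparable).
#'
#' @param original,generated expression matrices over the same genes.
#' @param original_stages,generated_stages optional stage labels for plotting.
#' @param seed seed for the gene-view subsampling.
#' @return list with `sample_scores` (data frame: PC1, PC2, source, stage),
#'   `sample_var_explained`, `gene_scores` (PC1, PC2, source),
#'   `gene_var_explained`.
#' @export
pca_embed <- function(original, generated, original_stages = NULL,
                      generated_stages = NULL, seed = 1) {
  original <- as.matrix(original)
  generated <- as.matrix(generated)
  assert_that(ncol(original) == ncol(generated),
              "original and generated must share the gene set")
  pooled <- rbind(original, generated)
  assert_that(nrow(pooled) >= 3, "need at least 3 samples")
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- data.frame(PC1 = pc$x[, 1],
                       PC2 = if (k >= 2) pc$x[, 2] else 0,
                       source = rep(c("original", "generated"),
                                    c(nrow(original), nrow(generated))),
                       stage = c(original_stages %||%
                                   rep(NA_integer_, nrow(original)),
                                 generated_stages %||%
                                   rep(NA_integer_, nrow(generated))),
                       stringsAsFactors = FALSE)
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)

  n_common <- min(nrow(original), nrow(generated))
  gpool <- with_seed(derive_seed(seed, 53), {
    go <- t(original[sample(nrow(original), n_common), , drop = FALSE])
    gg <- t(generated[sample(nrow(generated), n_common), , drop = FALSE])
    rbind(go, gg)
  })
  gpc <- stats::prcomp(gpool, center = TRUE, scale. = FALSE)
  gk <- min(2, ncol(gpc$x))
  gene_scores <- data.frame(PC1 = gpc$x[, 1],
                            PC2 = if (gk >= 2) gpc$x[, 2] else 0,
                            source = rep(c("original", "generated"),
                                         each = ncol(original)),
                            stringsAsFactors = FALSE)
  list(sample_scores = scores,
       sample_var_explained = var_expl,
       gene_scores = gene_scores,
       gene_var_explained = gpc$sdev^2 / sum(gpc$sdev^2))
}

# Stage-stratified subsample of a cohort: round(fraction * n_s) per stage.
subsample_cohort <- function(cohort, fraction, seed) {
  if (fraction >= 1) return(cohort)
  ids <- with_seed(seed, {
    unlist(lapply(sort(unique(cohort$stages)), function(s) {
      pool <- cohort$sample_ids[cohort$stages == s]
      k <- round(fraction * length(pool))
      if (k < 2) {
        stop(sprintf(
          "fraction %.2f leaves %d sample(s) of stage %d; need >= 2",
          fraction, k, s), call. = FALSE)
      }
      sample(pool, k)
    }), use.names = FALSE)
  })
  subset_cohort(cohort, sort(ids))
}

#' Subsampling experiment: augmentation benefit on shrinking cohorts
#'
#' For each fraction, draws a stage-stratified subsample of the cohort and runs
#' two arms through the usual cycle with the 1D-CNN: `O` (selected genes, no
#' augmentation — the FS variant) and `G` (GAN-augmented at `fold`). At
#' fraction 1.0 the `O` arm coincides with the plain FS experiment.
#'
#' @param cohort a [cohort_dataset()].
#' @param fractions fractions of each stage to keep
#'   (default `c(1, 0.5, 0.3, 0.1)`).
#' @param fold GAN fold for the `G` arm (default 5).
#' @param config an [experiment_config()]; its `repeats`, `base_seed`, `fs`,
#'   `gan` and `cnn` fields are used.
#' @param selected_genes optional precomputed selection.
#' @return a `results_table` with columns `fraction`, `arm`, `repeat`,
#'   `accuracy`, `macro_f1`, `error`.
#' @export
subsample_experiment <- function(cohort, fractions = c(1, 0.5, 0.3, 0.1),
                                 fold = 5, config = experiment_config(),
                                 selected_genes = NULL) {
  sel <- select_or_use(cohort, config, selected_genes)
  gan_variant <- paste0("GAN", fold)
  rows <- list()
  for (f in fractions) {
    for (r in seq_len(config$repeats)) {
      sub <- subsample_cohort(cohort, f,
                              derive_seed(config$base_seed, 401,
                                          round(1000 * f), r))
      split_all <- stratified_split(sub, config$train_fraction,
                                    seed = derive_seed(config$base_seed, r))
      split_sel <- restrict_genes(split_all, sel)
      for (arm in c("O", "G")) {
        v <- if (arm == "O") "FS" else gan_variant
        cell <- run_cell(split_all, split_sel, v, "1DCNN", config, r)
        row <- data.frame(fraction = f, arm = arm, accuracy = cell$accuracy,
                          macro_f1 = cell$macro_f1, error = cell$error,
                          stringsAsFactors = FALSE)
        row[["repeat"]] <- r
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("fraction", "arm", "repeat", "accuracy", "macro_f1", "error")]
  attr(out, "selected_genes") <- sel
  class(out) <- c("results_table", "data.frame")
  out
}

#' Sweep the GAN augmentation fold
#'
#' Runs the GANk variant with the 1D-CNN for each fold, sharing splits across
#' folds within a repeat; the fold-1 rows coincide with the `GAN1` variant of
#' [run_experiment()] under the same `base_seed`.
#'
#' @param cohort a [cohort_dataset()].
#' @param folds integer folds to sweep
#'   (default `c(1, 5, 10, 20, 30, 50, 70, 100)`).
#' @param config an [experiment_config()].
#' @param selected_genes optional precomputed selection.
#' @return a `results_table` with columns `fold`, `repeat`, `accuracy`,
#'   `macro_f1`, `error`.
#' @export
fold_sweep <- function(cohort, folds = c(1, 5, 10, 20, 30, 50, 70, 100),
                       config = experiment_config(), selected_genes = NULL) {
  sel <- select_or_use(cohort, config, selected_genes)
  rows <- list()
  for (r in seq_len(config$repeats)) {
    split_all <- stratified_split(cohort, config$train_fraction,
                                  seed = derive_seed(config$base_seed, r))
    split_sel <- restrict_genes(split_all, sel)
    for (f in folds) {
      cell <- run_cell(split_all, split_sel, paste0("GAN", f), "1DCNN",
                       config, r)
      row <- data.frame(fold = f, accuracy = cell$accuracy,
                        macro_f1 = cell$macro_f1, error = cell$error,
                        stringsAsFactors = FALSE)
      row[["repeat"]] <- r
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("fold", "repeat", "accuracy", "macro_f1", "error")]
  attr(out, "selected_genes") <- sel
  class(out) <- c("results_table", "data.frame")
  out
}
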