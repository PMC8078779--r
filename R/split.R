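# Stratified train/test splitting.

#' Stratified train/test split of a cohort
#'
#' Splits a cohort into train and test partitions, sampling within each stage
#' so that every stage is represented on both sides. The per-stage training
#' count is `round(train_fraction * n_stage)`, clamped to leave at least one
#' sample of the stage in each partition.
#'
#' @param cohort a [cohort_dataset()].
#' @param train_fraction fraction of each stage assigned to training
#'   (default 0.7).
#' @param seed integer seed; the same seed always yields the same partition.
#' @return An object of class `split_dataset`: list with `train` and `test`
#'   cohort views plus `train_fraction` and `seed`.
#' @examples
#' syn <- make_synthetic_cohort(synthetic_config(stage_counts = c(10, 10, 10, 10),
#'                                               n_genes = 20, seed = 1))
#' sp <- stratified_split(syn$cohort, 0.7, seed = 1)
#' table(sp$train$stages)  # 7 per stage
#' @export
stratified_split <- function(cohort, train_fraction = 0.7, seed) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0,1)")
  counts <- table(cohort$stages)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop(sprintf("stage(s) with fewer than 2 samples cannot be split: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  train_ids <- with_seed(seed, {
    unlist(lapply(sort(unique(cohort$stages)), function(s) {
      ids <- cohort$sample_ids[cohort$stages == s]
      k <- round(train_fraction * length(ids))
      k <- min(max(k, 1L), length(ids) - 1L)
      sample(ids, k)
    }), use.names = FALSE)
  })
  test_ids <- setdiff(cohort$sample_ids, train_ids)
  structure(
    list(train = subset_cohort(cohort, sort(train_ids)),
         test = subset_cohort(cohort, sort(test_ids)),
         train_fraction = train_fraction, seed = seed),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("split_dataset (fraction %.2f, seed %s): %d train / %d test\n",
              x$train_fraction, format(x$seed),
              length(x$train$sample_ids), length(x$test$sample_ids)))
  invisible(x)
}

# Restrict the expression matrices of a split to a gene subset (selection
# order is preserved; the 1D-CNN consumes genes in this order).
restrict_genes <- function(split, gene_ids) {
  missing <- setdiff(gene_ids, colnames(split$train$expression))
  assert_that(length(missing) == 0,
              paste("genes absent from expression matrix:",
                    paste(missing, collapse = ", ")))
  out <- split
  out$train$expression <- split$train$expression[, gene_ids, drop = FALSE]
  out$test$expression <- split$test$expression[, gene_ids, drop = FALSE]
  out
}
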