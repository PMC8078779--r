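# normalization: batch-effect adjustment (parametric empirical-Bayes ComBat).

#' Adjust an expression matrix for batch effects
#'
#' Applies parametric ComBat (gene-wise standardisation, empirical-Bayes
#' shrinkage of per-batch location and scale, back-transformation) via
#' \code{sva::ComBat}. With a single batch (or no batch labels) the input is
#' returned unchanged with a message — there is nothing to correct. Genes with
#' zero variance inside any batch cannot be standardised and pass through
#' unadjusted with a warning. When fewer than two adjustable genes remain, the
#' empirical-Bayes priors are undefined and a direct (non-shrunken) per-batch
#' location/scale adjustment is used instead.
#'
#' @param expression numeric matrix, samples x genes.
#' @param batch vector of batch labels, one per sample (row). `NULL` skips
#'   adjustment.
#' @param stages optional integer stage labels supplied as a model covariate so
#'   that stage-associated signal is protected during adjustment (off by
#'   default).
#' @return adjusted matrix of the same dimensions and dimnames.
#' @export
combat_adjust <- function(expression, batch = NULL, stages = NULL) {
  expression <- as.matrix(expression)
  if (is.null(batch) || length(unique(batch)) < 2) {
    message("combat_adjust: fewer than 2 batches; returning input unchanged")
    return(expression)
  }
  assert_that(length(batch) == nrow(expression),
              "batch labels must match the sample (row) count")
  batch <- as.character(batch)
  counts <- table(batch)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    stop(sprintf("batch(es) with a single sample cannot be adjusted: %s",
                 paste(singletons, collapse = ", ")), call. = FALSE)
  }

  # genes that are constant within any batch cannot be standardised there
  constant <- rep(FALSE, ncol(expression))
  for (b in unique(batch)) {
    sub <- expression[batch == b, , drop = FALSE]
    constant <- constant | (col_sds(sub) == 0)
  }
  if (any(constant)) {
    warning(sprintf(
      "%d gene(s) constant within a batch pass through unadjusted",
      sum(constant)))
  }
  adj_idx <- which(!constant)
  out <- expression
  if (length(adj_idx) == 0) return(out)

  mod <- NULL
  if (!is.null(stages)) mod <- stats::model.matrix(~ factor(stages))

  if (length(adj_idx) >= 2) {
    dat <- t(expression[, adj_idx, drop = FALSE])  # ComBat wants genes x samples
    adj <- sva::ComBat(dat = dat, batch = batch, mod = mod, par.prior = TRUE)
    out[, adj_idx] <- t(adj)
  } else {
    out[, adj_idx] <- location_scale_adjust(expression[, adj_idx, drop = FALSE],
                                            batch)
  }
  out
}

# Direct per-batch location/scale adjustment (the no-pooling limit of the
# empirical-Bayes estimator): each batch is standardised with its own mean/SD
# and rescaled to the pooled gene moments.
location_scale_adjust <- function(x, batch) {
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    grand <- mean(v)
    pooled_sd <- sqrt(mean(unlist(lapply(split(v, batch), stats::var))))
    for (b in unique(batch)) {
      i <- batch == b
      out[i, j] <- (v[i] - mean(v[i])) / stats::sd(v[i]) * pooled_sd + grand
    }
  }
  out
}
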