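# augmentation baselines: per-stage Gaussian sampling (MS), SMOTE, and
# denoising-autoencoder expansion (DA).

#' Mean/SD Gaussian baseline augmentation (MS)
#'
#' For each stage s, draws `n_s` synthetic samples with gene g distributed
#' Normal(stage mean, stage SD / 2). The output contains synthetic samples
#' only, one per original training sample, so stage ratios are preserved.
#'
#' @param split a [stratified_split()] result.
#' @param seed integer seed.
#' @return an `augmented_training_set` (method `"MS"`).
#' @export
augment_ms <- function(split, seed = 1) {
  train <- split$train
  stages <- sort(unique(train$stages))
  with_seed(derive_seed(seed, 31337), {
    pieces <- lapply(stages, function(s) {
      x <- train$expression[train$stages == s, , drop = FALSE]
      assert_that(nrow(x) >= 2, sprintf("stage %d has < 2 samples", s))
      mu <- colMeans(x)
      half_sd <- col_sds(x) / 2
      n_s <- nrow(x)
      matrix(stats::rnorm(n_s * ncol(x), mean = rep(mu, each = n_s),
                          sd = rep(half_sd, each = n_s)),
             n_s, ncol(x), dimnames = list(NULL, colnames(x)))
    })
    expr <- do.call(rbind, pieces)
    labels <- rep(stages, vapply(pieces, nrow, integer(1)))
    rownames(expr) <- sprintf("MS_%05d", seq_len(nrow(expr)))
    augmented_training_set(expr, labels, "MS")
  })
}

#' SMOTE oversampling to the majority-stage count
#'
#' Every stage is brought up to the majority stage's training count by the
#' basic SMOTE rule: pick a stage sample x_i, pick one of its k nearest
#' same-stage neighbours x_nn (Euclidean distance), and emit
#' `x_i + u * (x_nn - x_i)` with u ~ Uniform(0,1). Original samples are kept,
#' so a balanced input is returned unchanged.
#'
#' @param split a [stratified_split()] result.
#' @param k_neighbors neighbourhood size (default 5, reduced to `n_s - 1` for
#'   small stages).
#' @param seed integer seed.
#' @return an `augmented_training_set` (method `"SMOTE"`) with the majority
#'   count in every stage.
#' @export
augment_smote <- function(split, k_neighbors = 5, seed = 1) {
  train <- split$train
  counts <- table(train$stages)
  if (any(counts < 2)) {
    stop(sprintf("stage(s) with a single sample cannot be oversampled: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")),
         call. = FALSE)
  }
  target <- max(counts)
  stages <- sort(unique(train$stages))
  with_seed(derive_seed(seed, 65537), {
    pieces <- lapply(stages, function(s) {
      x <- train$expression[train$stages == s, , drop = FALSE]
      n_s <- nrow(x)
      need <- target - n_s
      if (need == 0) return(x)
      k <- min(k_neighbors, n_s - 1)
      d <- as.matrix(stats::dist(x))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
      base_idx <- sample.int(n_s, need, replace = TRUE)
      nn_idx <- vapply(base_idx, function(i) nn[i, sample.int(k, 1)],
                       integer(1))
      u <- stats::runif(need)
      synth <- x[base_idx, , drop = FALSE] +
        u * (x[nn_idx, , drop = FALSE] - x[base_idx, , drop = FALSE])
      rownames(synth) <- sprintf("SMOTE_s%d_%04d", s, seq_len(need))
      rbind(x, synth)
    })
    expr <- do.call(rbind, pieces)
    labels <- rep(stages, vapply(pieces, nrow, integer(1)))
    augmented_training_set(expr, labels, "SMOTE")
  })
}

#' Denoising-autoencoder expansion sample count
#'
#' The DA baseline turns n training samples with m genes into
#' `n * floor(m / 5) + n` samples: the originals plus, for every sample, one
#' reconstruction per disjoint 5-gene corruption window.
#'
#' @param n number of training samples.
#' @param m number of genes.
#' @return integer-valued count `n * floor(m/5) + n`.
#' @examples
#' da_sample_count(659, 19738)  # 2601732
#' @export
da_sample_count <- function(n, m) {
  assert_that(is_count(n), "n must be a positive integer")
  assert_that(is_count(m), "m must be a positive integer")
  n * floor(m / 5) + n
}

# Window corruption: copy j (1-based) zeroes genes (5(j-1)+1)..(5(j-1)+5).
corrupt_window <- function(x, j) {
  x[, (5 * (j - 1) + 1):(5 * j)] <- 0
  x
}

#' Denoising-autoencoder expansion (DA)
#'
#' Trains a single-hidden-layer denoising autoencoder (256 ReLU units, linear
#' output, mean-squared-error loss, Adam) on the training expression, using
#' window-corrupted inputs against clean targets. The augmented set is the
#' originals plus, for each sample, `floor(m/5)` reconstructions of copies in
#' which corruption window j zeroes genes `[5(j-1)+1, 5j]`; labels are
#' inherited from the source sample. Total count is [da_sample_count()].
#'
#' @param split a [stratified_split()] result.
#' @param seed integer seed.
#' @param epochs training epochs (default 100).
#' @param hidden_units hidden width (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @return an `augmented_training_set` (method `"DA"`) with a `loss_trace`
#'   element (per-epoch reconstruction MSE).
#' @export
augment_da <- function(split, seed = 1, epochs = 100, hidden_units = 256,
                       learning_rate = 1e-3, batch_size = 32) {
  train <- split$train
  x <- train$expression
  m <- ncol(x)
  n <- nrow(x)
  n_windows <- floor(m / 5)
  scaler <- scaler_fit(x)
  xs <- scaler_apply(scaler, x)

  with_seed(derive_seed(seed, 262147), {
    net <- mlp_new(c(m, hidden_units, m), c("relu", "linear"))
    # training pairs: corrupted copies -> clean originals (plus the identity
    # pair so uncorrupted inputs reconstruct well too)
    if (n_windows > 0) {
      Xin <- do.call(rbind, c(list(xs), lapply(seq_len(n_windows), function(j) {
        corrupt_window(xs, j)
      })))
      Xtar <- do.call(rbind, rep(list(xs), n_windows + 1))
    } else {
      Xin <- xs
      Xtar <- xs
    }
    mse_grad <- function(out, Y) {
      diff <- out - Y
      list(loss = mean(diff^2), dpre = 2 * diff / (nrow(Y) * ncol(Y)))
    }
    fit <- mlp_train(net, Xin, Xtar, epochs, batch_size, learning_rate,
                     mse_grad)
    net <- fit$net

    pieces <- list(x)
    labels <- list(train$stages)
    for (j in seq_len(n_windows)) {
      rec <- mlp_forward(net, corrupt_window(xs, j))$out
      pieces[[j + 1]] <- scaler_invert(scaler, rec)
      labels[[j + 1]] <- train$stages
    }
    expr <- do.call(rbind, pieces)
    colnames(expr) <- colnames(x)
    rownames(expr) <- sprintf("DA_%06d", seq_len(nrow(expr)))
    out <- augmented_training_set(expr, unlist(labels), "DA")
    out$loss_trace <- fit$trace
    out
  })
}
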