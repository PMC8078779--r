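# classifiers: 1D-CNN, DNN and random forest behind one train/predict/evaluate
# interface.

#' 1D-CNN classifier configuration
#'
#' Two valid-padding convolution layers (20 then 40 filters, kernel size 5),
#' each followed by ReLU and max-pooling of size 2 (ceil mode, so a trailing
#' partial window is kept), a flatten, a 64-unit ReLU dense layer and a
#' 4-class softmax output; categorical cross-entropy, Adam. The minimum input
#' length for the default architecture is 13 genes.
#'
#' @param filters filter counts of the two convolution layers (default
#'   `c(20, 40)`).
#' @param kernel_size convolution kernel width (default 5).
#' @param pool_size max-pool window/stride (default 2).
#' @param dense_units width of the dense hidden layer (default 64).
#' @param epochs training epochs (default 1000).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed integer seed.
#' @return a `cnn_config` list (kind `"1DCNN"`).
#' @export
cnn_config <- function(filters = c(20, 40), kernel_size = 5, pool_size = 2,
                       dense_units = 64, epochs = 1000, batch_size = 32,
                       learning_rate = 1e-3, seed = 1) {
  assert_that(length(filters) == 2 && all(filters >= 1),
              "filters must give two positive counts")
  assert_that(is_count(kernel_size, 2), "kernel_size must be >= 2")
  assert_that(is_count(pool_size, 2), "pool_size must be >= 2")
  structure(list(kind = "1DCNN", filters = as.integer(filters),
                 kernel_size = kernel_size, pool_size = pool_size,
                 dense_units = dense_units, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = seed),
            class = c("cnn_config", "classifier_config"))
}

#' DNN classifier configuration
#'
#' A multilayer perceptron with ReLU hidden layers of sizes 64, 32 and 4 and a
#' 4-class softmax output; categorical cross-entropy, Adam.
#'
#' @param hidden hidden-layer sizes (default `c(64, 32, 4)`).
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed integer seed.
#' @return a `dnn_config` list (kind `"DNN"`).
#' @export
dnn_config <- function(hidden = c(64, 32, 4), epochs = 200, batch_size = 32,
                       learning_rate = 1e-3, seed = 1) {
  assert_that(length(hidden) >= 1 && all(hidden >= 1),
              "hidden sizes must be positive")
  structure(list(kind = "DNN", hidden = as.integer(hidden), epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = seed),
            class = c("dnn_config", "classifier_config"))
}

#' Random-forest classifier configuration
#'
#' @param n_trees number of trees (default 100).
#' @param oob_score keep the out-of-bag error estimate (default `TRUE`).
#' @param seed integer seed (default 123456).
#' @return an `rf_config` list (kind `"RF"`).
#' @export
rf_config <- function(n_trees = 100, oob_score = TRUE, seed = 123456) {
  assert_that(is_count(n_trees), "n_trees must be >= 1")
  structure(list(kind = "RF", n_trees = n_trees, oob_score = oob_score,
                 seed = seed),
            class = c("rf_config", "classifier_config"))
}

# Accept an augmented_training_set, a cohort_dataset or a plain list with
# $expression and $stages.
as_training_set <- function(x) {
  assert_that(!is.null(x$expression) && !is.null(x$stages),
              "training set needs $expression and $stages")
  list(expression = as.matrix(x$expression), stages = as.integer(x$stages))
}

one_hot <- function(stages) {
  Y <- matrix(0, length(stages), 4)
  Y[cbind(seq_along(stages), stages)] <- 1
  Y
}

#' Train a stage classifier
#'
#' Dispatches on the configuration class: [cnn_config()] and [dnn_config()]
#' train the neural networks by minibatch Adam on standardised inputs (the
#' per-gene training scaler is stored on the model and applied at prediction
#' time); [rf_config()] fits a `ranger` random forest on the raw values.
#' All three are exactly reproducible given the config seed.
#'
#' @param train_set an `augmented_training_set`, [cohort_dataset()] or list
#'   with `$expression` (samples x genes) and `$stages` (integers 1-4).
#' @param config a classifier configuration.
#' @return An object of class `trained_classifier` with elements `kind`,
#'   `fit`, `feature_order`, `config` and, for the neural networks, `scaler`
#'   and `loss_trace`.
#' @export
train_classifier <- function(train_set, config) {
  ts <- as_training_set(train_set)
  assert_that(length(unique(ts$stages)) >= 2,
              "training set has a single class; need >= 2 stages")
  m <- ncol(ts$expression)
  out <- switch(
    config$kind,
    "1DCNN" = {
      min_m <- cnn_min_features(config$kernel_size, config$pool_size)
      if (m < min_m) {
        stop(sprintf(paste0(
          "1D-CNN needs at least %d input genes for kernel %d / pool %d ",
          "(got %d): the second pooling stage would be empty"),
          min_m, config$kernel_size, config$pool_size, m), call. = FALSE)
      }
      scaler <- scaler_fit(ts$expression)
      X <- scaler_apply(scaler, ts$expression)
      fit <- with_seed(derive_seed(config$seed, 811), {
        net <- cnn_new(m, config)
        cnn_train(net, X, one_hot(ts$stages), config$epochs,
                  config$batch_size, config$learning_rate)
      })
      list(fit = fit$net, scaler = scaler, loss_trace = fit$trace)
    },
    "DNN" = {
      scaler <- scaler_fit(ts$expression)
      X <- scaler_apply(scaler, ts$expression)
      ce_grad <- function(out, Y) {
        eps <- 1e-12
        list(loss = -mean(log(pmax(rowSums(out * Y), eps))),
             dpre = (out - Y) / nrow(Y))
      }
      fit <- with_seed(derive_seed(config$seed, 1021), {
        sizes <- c(m, config$hidden, 4)
        acts <- c(rep("relu", length(config$hidden)), "softmax")
        net <- mlp_new(sizes, acts)
        mlp_train(net, X, one_hot(ts$stages), config$epochs,
                  config$batch_size, config$learning_rate, ce_grad)
      })
      list(fit = fit$net, scaler = scaler, loss_trace = fit$trace)
    },
    "RF" = {
      fit <- ranger::ranger(x = ts$expression, y = factor(ts$stages),
                            num.trees = config$n_trees,
                            oob.error = config$oob_score,
                            seed = config$seed, num.threads = 1)
      list(fit = fit, scaler = NULL, loss_trace = NULL)
    },
    stop("unknown classifier kind: ", config$kind)
  )
  structure(c(out, list(kind = config$kind,
                        feature_order = colnames(ts$expression),
                        config = config)),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("trained_classifier (%s): %d input genes\n", x$kind,
              length(x$feature_order)))
  invisible(x)
}

check_feature_order <- function(model, newdata) {
  if (is.null(colnames(newdata)) ||
      identical(colnames(newdata), model$feature_order)) {
    return(invisible())
  }
  missing <- setdiff(model$feature_order, colnames(newdata))
  extra <- setdiff(colnames(newdata), model$feature_order)
  if (length(missing) || length(extra) ||
      !identical(colnames(newdata), model$feature_order)) {
    stop(sprintf(
      "feature mismatch with training order; missing: %s; extra: %s",
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"),
      call. = FALSE)
  }
}

#' Predict stages for new samples
#'
#' @param object a [train_classifier()] result.
#' @param newdata expression matrix with the training gene order.
#' @param type `"class"` for stage labels, `"prob"` for class probabilities
#'   (neural networks only).
#' @param ... unused.
#' @return integer stage labels, or a samples x 4 probability matrix whose
#'   rows sum to 1.
#' @export
predict.trained_classifier <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  check_feature_order(object, newdata)
  if (object$kind == "RF") {
    assert_that(type == "class",
                "class probabilities are available for the neural networks only")
    pr <- stats::predict(object$fit, data = newdata, num.threads = 1)
    return(as.integer(as.character(pr$predictions)))
  }
  X <- scaler_apply(object$scaler, newdata)
  probs <- if (object$kind == "1DCNN") {
    cnn_forward(object$fit, X)$probs
  } else {
    mlp_forward(object$fit, X)$out
  }
  if (type == "prob") {
    colnames(probs) <- paste0("stage", 1:4)
    return(probs)
  }
  apply(probs, 1, which.max)
}

#' Accuracy, macro-F1 and the confusion matrix of a fitted classifier
#'
#' Accuracy is the fraction of correct predictions. Macro-F1 is the unweighted
#' mean of per-class F1 scores; classes absent from both the truth and the
#' predictions are excluded from the mean, and a class that appears on one
#' side only contributes an F1 of 0.
#'
#' @param model a [train_classifier()] result.
#' @param test_set a [cohort_dataset()] or list with `$expression` and
#'   `$stages`; must be non-empty.
#' @return list with `accuracy`, `macro_f1` and the 4x4 `confusion` table
#'   (rows = truth, columns = prediction).
#' @export
evaluate_classifier <- function(model, test_set) {
  ts <- as_training_set(test_set)
  assert_that(nrow(ts$expression) > 0, "test set is empty")
  pred <- predict(model, ts$expression)
  stage_metrics(ts$stages, pred)
}

#' Stage-classification metrics from label vectors
#'
#' @param truth integer truth labels (1-4).
#' @param pred integer predicted labels (1-4).
#' @return list with `accuracy`, `macro_f1`, `confusion`.
#' @export
stage_metrics <- function(truth, pred) {
  assert_that(length(truth) == length(pred) && length(truth) > 0,
              "truth and pred must be equal-length, non-empty")
  cm <- table(factor(truth, levels = 1:4), factor(pred, levels = 1:4))
  list(accuracy = mean(truth == pred), macro_f1 = macro_f1_from_confusion(cm),
       confusion = cm)
}

macro_f1_from_confusion <- function(cm) {
  f1 <- numeric(0)
  for (k in seq_len(nrow(cm))) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    if (tp + fn + fp == 0) next  # class absent from both truth and prediction
    f1 <- c(f1, 2 * tp / (2 * tp + fp + fn))
  }
  mean(f1)
}
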