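test_that("random forest with a pinned seed is exactly reproducible", {
  ts <- separable_set(n_per_class = 20, seed = 1)
  m1 <- train_classifier(ts, rf_config())  # random_state 123456
  m2 <- train_classifier(ts, rf_config())
  newx <- separable_set(n_per_class = 10, seed = 2)$expression
  expect_identical(predict(m1, newx), predict(m2, newx))
})

test_that("the 1D-CNN enforces its minimum input length", {
  ts <- separable_set(n_per_class = 10, n_genes = 10, seed = 3)
  expect_error(train_classifier(ts, cnn_config(epochs = 1)),
               "at least 13")
  # 13 genes is exactly viable with ceil-mode pooling
  ts13 <- separable_set(n_per_class = 10, n_genes = 13, seed = 3)
  m <- train_classifier(ts13, cnn_config(epochs = 2, seed = 1))
  expect_length(predict(m, ts13$expression), 40)
})

test_that("the DNN fits linearly separable 4-class data", {
  for (s in 1:3) {
    ts <- separable_set(seed = s)  # 200 samples, 20 genes
    m <- train_classifier(ts, dnn_config(epochs = 200, seed = s))
    acc <- mean(predict(m, ts$expression) == ts$stages)
    expect_gte(acc, 0.95)
  }
})

test_that("prediction contracts hold: probabilities, row independence, recall", {
  ts <- separable_set(n_per_class = 15, seed = 4)
  m <- train_classifier(ts, dnn_config(epochs = 150, seed = 2))
  p <- predict(m, ts$expression, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_equal(dim(p), c(60, 4))

  # permuting input rows permutes predictions identically
  perm <- sample(nrow(ts$expression))
  expect_identical(predict(m, ts$expression)[perm],
                   predict(m, ts$expression[perm, ]))

  # an overfit model memorises its training labels
  tiny <- separable_set(n_per_class = 3, sep = 6, seed = 5)
  mo <- train_classifier(tiny, dnn_config(epochs = 600, seed = 1))
  expect_equal(predict(mo, tiny$expression), tiny$stages)

  # feature mismatch is reported with the offending genes
  wrong <- ts$expression
  colnames(wrong)[1] <- "not_a_gene"
  expect_error(predict(m, wrong), "not_a_gene")
})

test_that("accuracy and macro-F1 match hand-computed references", {
  # perfect prediction
  r <- stage_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$accuracy, 1.0)
  expect_equal(r$macro_f1, 1.0)

  # all-"stage 1" on a balanced 4-class set: per-class F1 = (0.4, 0, 0, 0)
  truth <- rep(1:4, each = 10)
  r2 <- stage_metrics(truth, rep(1L, 40))
  expect_equal(r2$accuracy, 0.25)
  expect_equal(r2$macro_f1, 0.10, tolerance = 1e-12)

  # fixed confusion matrix worked through by hand:
  # truth 1: 5 correct, 1 -> 2 ; truth 2: 3 correct, 2 -> 3
  # truth 3: 4 correct        ; truth 4: 1 correct, 1 -> 1
  truth <- c(rep(1, 6), rep(2, 5), rep(3, 4), rep(4, 2))
  pred <- c(rep(1, 5), 2, rep(2, 3), 3, 3, rep(3, 4), 1, 4)
  # F1_1 = 2*5/(10+1+1) = 10/12; F1_2 = 2*3/(6+1+2) = 6/9
  # F1_3 = 2*4/(8+2+0) = 8/10 ; F1_4 = 2*1/(2+0+1) = 2/3
  hand <- mean(c(10 / 12, 6 / 9, 8 / 10, 2 / 3))
  r3 <- stage_metrics(truth, pred)
  expect_equal(r3$accuracy, 13 / 17, tolerance = 1e-12)
  expect_equal(r3$macro_f1, hand, tolerance = 1e-12)

  # classes absent from both truth and prediction are excluded
  r4 <- stage_metrics(c(1, 1, 2), c(1, 1, 2))
  expect_equal(r4$macro_f1, 1.0)
})

test_that("metrics stay in [0,1] and zero-signal data scores at chance", {
  set.seed(6)
  for (i in 1:20) {
    truth <- sample(1:4, 15, replace = TRUE)
    pred <- sample(1:4, 15, replace = TRUE)
    r <- stage_metrics(truth, pred)
    expect_true(r$accuracy >= 0 && r$accuracy <= 1)
    expect_true(r$macro_f1 >= 0 && r$macro_f1 <= 1)
    if (all(truth == pred)) expect_equal(r$macro_f1, 1)
  }

  # balanced null cohort: mean RF accuracy over 10 splits ~ majority rate 0.25
  syn <- make_synthetic_cohort(
    synthetic_config(effect_size = 0, mut_gradient = 1, n_genes = 30,
                     n_informative = 5, seed = 12))
  accs <- sapply(1:10, function(r) {
    sp <- stratified_split(syn$cohort, 0.7, seed = r)
    m <- train_classifier(list(expression = sp$train$expression,
                               stages = sp$train$stages), rf_config())
    evaluate_classifier(m, sp$test)$accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.25), 3 * max(se, 0.01))
})

test_that("single-class training sets are rejected", {
  x <- matrix(rnorm(60), 4, 15, dimnames = list(NULL, paste0("g", 1:15)))
  expect_error(train_classifier(list(expression = x, stages = rep(2, 4)),
                                rf_config()), "single class|>= 2")
})
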