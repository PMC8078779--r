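# Harness tests run at deliberately tiny scale (few genes, 1-2 epochs); the
# properties checked are structural, not about classification quality.

eval_cohort <- function(seed = 20) {
  tiny_cohort(counts = c(8, 8, 8, 8), n_genes = 20, n_informative = 14,
              seed = seed)
}

fast_config <- function(...) {
  experiment_config(..., gan = gan_config(epochs = 2, hidden_units = 8),
                    cnn = cnn_config(epochs = 2),
                    dnn = dnn_config(epochs = 2),
                    da_epochs = 2)
}

test_that("run_experiment is deterministic and shares splits across variants", {
  cohort <- eval_cohort()
  sel <- colnames(cohort$expression)[1:14]
  cfg <- fast_config(variants = "FS", classifiers = "RF", repeats = 2,
                     base_seed = 3)
  a <- run_experiment(cohort, cfg, selected_genes = sel)
  b <- run_experiment(cohort, cfg, selected_genes = sel)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$macro_f1, b$macro_f1)

  # FS rows are unchanged when Ori runs alongside (same split per repeat)
  cfg2 <- fast_config(variants = c("Ori", "FS"), classifiers = "RF",
                      repeats = 2, base_seed = 3)
  ab <- run_experiment(cohort, cfg2, selected_genes = sel)
  expect_equal(ab$accuracy[ab$variant == "FS"], a$accuracy)
  expect_equal(nrow(ab), 4)  # 2 variants x 1 classifier x 2 repeats
})

test_that("failed cells are recorded as missing, not dropped", {
  cohort <- eval_cohort()
  sel <- colnames(cohort$expression)[1:5]  # below the CNN minimum
  cfg <- fast_config(variants = "FS", classifiers = c("1DCNN", "RF"),
                     repeats = 1, base_seed = 1)
  res <- run_experiment(cohort, cfg, selected_genes = sel)
  cnn_row <- res[res$classifier == "1DCNN", ]
  expect_true(is.na(cnn_row$accuracy))
  expect_match(cnn_row$error, "at least 13")
  expect_false(is.na(res$accuracy[res$classifier == "RF"]))
})

test_that("aggregates are recomputable from the raw rows", {
  cohort <- eval_cohort()
  sel <- colnames(cohort$expression)[1:14]
  cfg <- fast_config(variants = c("FS", "MS"), classifiers = "RF",
                     repeats = 3, base_seed = 5)
  res <- run_experiment(cohort, cfg, selected_genes = sel)
  s <- summarize_results(res)
  for (v in c("FS", "MS")) {
    rows <- res$accuracy[res$variant == v]
    expect_equal(s$accuracy_mean[s$variant == v], mean(rows))
    expect_equal(s$accuracy_sd[s$variant == v], sd(rows))
    expect_equal(s$n[s$variant == v], 3)
  }
})

test_that("Welch t-test wrapper matches the closed form and its conventions", {
  expect_equal(compare_ttest(c(0.5, 0.6, 0.55), c(0.5, 0.6, 0.55)), 1.0)

  a <- c(0.9, 0.9, 0.9, 0.9) + c(1, -1, 2, -2) * 1e-4
  b <- c(0.1, 0.1, 0.1, 0.1) + c(-1, 2, -2, 1) * 1e-4
  expect_lt(compare_ttest(a, b), 1e-6)

  # hand-computed Welch statistic as an independent oracle
  x <- c(0.61, 0.58, 0.64, 0.57, 0.60)
  y <- c(0.52, 0.55, 0.49, 0.53)
  sx2 <- var(x) / length(x)
  sy2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df <- (sx2 + sy2)^2 / (sx2^2 / (length(x) - 1) + sy2^2 / (length(y) - 1))
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(compare_ttest(x, y), p_hand, tolerance = 1e-10)

  expect_error(compare_ttest(0.5, c(0.1, 0.2)), ">= 2")
})

test_that("PCA embedding handles rank-1 and duplicated inputs", {
  # data on a line: first component explains (essentially) everything
  t_par <- seq(0, 1, length.out = 12)
  line <- cbind(g1 = 2 * t_par, g2 = -t_par, g3 = 0.5 * t_par)
  emb <- pca_embed(line[1:6, ], line[7:12, ])
  expect_gte(emb$sample_var_explained[1], 0.999)

  # original == generated: the two clouds coincide exactly
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("g", 1:3)))
  emb2 <- pca_embed(x, x)
  o <- emb2$sample_scores[emb2$sample_scores$source == "original", 1:2]
  g <- emb2$sample_scores[emb2$sample_scores$source == "generated", 1:2]
  expect_equal(unname(as.matrix(o)), unname(as.matrix(g)))
  expect_equal(nrow(emb2$gene_scores), 6)
})

test_that("subsampling keeps stage proportions and refuses infeasible fractions", {
  cohort <- tiny_cohort(counts = c(10, 20, 14, 8), n_genes = 4,
                        n_informative = 2, seed = 30)
  sub <- omixaug:::subsample_cohort(cohort, 0.5, seed = 1)
  expect_equal(unname(c(table(sub$stages))), c(5L, 10L, 7L, 4L))
  expect_error(omixaug:::subsample_cohort(cohort, 0.1, seed = 1), ">= 2")
})

test_that("fraction-1.0 O-arm reproduces the plain FS experiment", {
  cohort <- eval_cohort(seed = 21)
  sel <- colnames(cohort$expression)[1:14]
  cfg <- fast_config(variants = "FS", classifiers = "1DCNN", repeats = 2,
                     base_seed = 7)
  fs <- run_experiment(cohort, cfg, selected_genes = sel)
  sub <- suppressWarnings(
    subsample_experiment(cohort, fractions = 1.0, fold = 1, config = cfg,
                         selected_genes = sel))
  o_arm <- sub[sub$arm == "O", ]
  expect_equal(o_arm$accuracy, fs$accuracy)
  expect_equal(o_arm$macro_f1, fs$macro_f1)
  expect_equal(nrow(sub), 4)  # 1 fraction x 2 arms x 2 repeats
})

test_that("fold_sweep agrees with the GAN1 variant under shared seeds", {
  cohort <- eval_cohort(seed = 22)
  sel <- colnames(cohort$expression)[1:14]
  cfg <- fast_config(variants = "GAN1", classifiers = "1DCNN", repeats = 2,
                     base_seed = 9)
  g1 <- suppressWarnings(run_experiment(cohort, cfg, selected_genes = sel))
  sw <- suppressWarnings(fold_sweep(cohort, folds = c(1, 2), config = cfg,
                                    selected_genes = sel))
  expect_equal(sw$accuracy[sw$fold == 1], g1$accuracy)
  expect_equal(nrow(sw), 4)  # |folds| x repeats
})
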