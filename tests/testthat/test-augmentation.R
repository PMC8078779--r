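test_that("GAN training and generation are exactly reproducible", {
  sp <- blob_split(c(20, 20), n_genes = 3, seed = 1)
  x1 <- sp$train$expression[sp$train$stages == 1, ]
  cfg <- gan_config(epochs = 20, batch_size = 16, seed = 5)
  g1 <- fit_stage_gan(x1, cfg, stage = 1)
  g2 <- fit_stage_gan(x1, cfg, stage = 1)
  expect_identical(sample_generator(g1, 10), sample_generator(g2, 10))
})

test_that("sample_generator honours count, shape and degenerate latent", {
  sp <- blob_split(c(30, 30), n_genes = 4, seed = 2)
  g <- fit_stage_gan(sp$train$expression[sp$train$stages == 1, ],
                     gan_config(epochs = 5, batch_size = 16, seed = 1), stage = 1)
  expect_error(sample_generator(g, 0), "positive")
  out <- sample_generator(g, 7)
  expect_equal(dim(out), c(7, 4))

  # constant training data: sd = 0 latent -> all generated rows identical
  const <- matrix(3, 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  gc <- fit_stage_gan(const, gan_config(epochs = 3, batch_size = 8, seed = 1), stage = 2)
  outc <- sample_generator(gc, 5)
  expect_true(all(apply(outc, 2, function(v) max(v) - min(v)) == 0))
})

test_that("GAN augmentation keeps exact stage ratios at every fold", {
  sp <- blob_split(c(110, 383, 152, 12), n_genes = 2, seed = 3)
  cfg <- gan_config(hidden_units = 8, epochs = 1, seed = 1)
  aug5 <- suppressWarnings(augment_gan(sp, 5, cfg))
  expect_equal(unname(c(table(aug5$stages))), c(550L, 1915L, 760L, 60L))
  expect_equal(nrow(aug5$expression), 3285L)

  aug1 <- suppressWarnings(augment_gan(sp, 1, cfg))
  expect_equal(nrow(aug1$expression), 657L)

  sp50 <- blob_split(c(20, 10, 10, 10), n_genes = 2, seed = 4)
  aug100 <- suppressWarnings(augment_gan(sp50, 100, cfg))
  expect_equal(nrow(aug100$expression), 5000L)
})

test_that("GAN rejects unusable stage data", {
  one <- matrix(1:4, 1, 4, dimnames = list(NULL, paste0("g", 1:4)))
  expect_error(fit_stage_gan(one, gan_config(epochs = 1)), "single sample")
  bad <- matrix(c(1, NA, 2, 3), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_stage_gan(bad, gan_config(epochs = 1, batch_size = 2)),
               "non-finite")
  small <- blob_split(c(5, 5), n_genes = 2, seed = 1)$train
  expect_warning(
    fit_stage_gan(small$expression[small$stages == 1, ],
                  gan_config(epochs = 1, batch_size = 32), stage = 1),
    "clamped")
})

test_that("MS draws from Normal(mean, sd/2) per stage and keeps counts", {
  sp <- blob_split(c(8, 8, 8, 8), n_genes = 3, seed = 5)
  sp$train$expression[sp$train$stages == 2, 1] <- 4.25  # constant within stage
  aug <- augment_ms(sp, seed = 1)
  expect_equal(unname(c(table(aug$stages))), rep(8L, 4))
  expect_true(all(aug$expression[aug$stages == 2, 1] == 4.25))

  # large draw: empirical sd approaches sd/2 within 5% per gene
  big <- blob_split(c(10000, 2), n_genes = 2, seed = 6)
  aug2 <- augment_ms(big, seed = 2)
  x <- big$train$expression[big$train$stages == 1, ]
  gen <- aug2$expression[aug2$stages == 1, ]
  ratio <- apply(gen, 2, sd) / (apply(x, 2, sd) / 2)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("SMOTE balances to the majority count and keeps originals", {
  sp <- blob_split(c(110, 383, 152, 12), n_genes = 2, seed = 7)
  aug <- augment_smote(sp, seed = 1)
  expect_equal(unname(c(table(aug$stages))), rep(383L, 4))
  expect_equal(nrow(aug$expression), 1532L)
  # originals are retained
  x1 <- sp$train$expression[sp$train$stages == 1, ]
  expect_true(all(rownames(x1) %in% rownames(aug$expression)))

  # balanced input -> no synthesis
  spb <- blob_split(c(9, 9, 9, 9), n_genes = 2, seed = 8)
  augb <- augment_smote(spb, seed = 1)
  expect_equal(sort(rownames(augb$expression)),
               sort(rownames(spb$train$expression)))

  sp1 <- fake_split(matrix(rnorm(6), 3, 2,
                           dimnames = list(paste0("S", 1:3), c("a", "b"))),
                    c(1, 1, 2))
  expect_error(augment_smote(sp1, seed = 1), "single sample")
})

test_that("the DA count rule matches the stated expansion formula", {
  expect_equal(da_sample_count(659, 19738), 2601732)
  expect_equal(da_sample_count(1, 4), 1)     # floor(4/5) = 0: originals only
  expect_equal(da_sample_count(10, 10), 30)  # 10 * 2 + 10
})

test_that("DA expansion emits originals plus window reconstructions", {
  sp <- blob_split(c(6, 6), n_genes = 10, seed = 9)
  aug <- augment_da(sp, seed = 1, epochs = 5)
  expect_equal(nrow(aug$expression), da_sample_count(12, 10))
  expect_equal(unname(c(table(aug$stages))), c(18L, 18L))  # labels inherited
  # the originals lead the output
  expect_equal(unname(aug$expression[1:12, ]),
               unname(sp$train$expression), tolerance = 1e-12)

  # corruption window j zeroes exactly genes 5(j-1)+1 .. 5j
  x <- matrix(rnorm(20), 2, 10)
  for (j in 1:2) {
    cor <- omixaug:::corrupt_window(x, j)
    win <- (5 * (j - 1) + 1):(5 * j)
    expect_true(all(cor[, win] == 0))
    expect_identical(cor[, -win], x[, -win])
  }
})

test_that("DA reconstruction error decreases over training", {
  for (s in 1:3) {
    sp <- blob_split(c(15, 15), n_genes = 20, delta = 2, seed = 10 + s)
    aug <- augment_da(sp, seed = s, epochs = 40)
    trace <- aug$loss_trace
    expect_lt(mean(tail(trace, 5)), mean(head(trace, 5)))
  }
})
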