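# augmentation (GAN): per-stage generative adversarial networks whose latent
# space is Normal(per-gene training mean, per-gene training SD).

#' GAN training configuration
#'
#' One hidden layer of `hidden_units` neurons for both the generator and the
#' discriminator. The latent dimensionality equals the gene count: each latent
#' coordinate is drawn from a Normal with that gene's training mean and
#' standard deviation.
#'
#' @param hidden_units hidden-layer width for both networks (default 256).
#' @param epochs adversarial training epochs (default 1000; values around
#'   900-1100 behave similarly on cohorts of this size).
#' @param batch_size minibatch size (default 32, clamped to the stage's sample
#'   count with a warning for very small stages).
#' @param learning_rate Adam learning rate for both networks (default 2e-4).
#' @param seed integer seed; training and generation are exactly reproducible.
#' @return a `gan_config` list.
#' @export
gan_config <- function(hidden_units = 256, epochs = 1000, batch_size = 32,
                       learning_rate = 2e-4, seed = 1) {
  assert_that(is_count(hidden_units), "hidden_units must be >= 1")
  assert_that(is_count(epochs), "epochs must be >= 1")
  assert_that(is_count(batch_size), "batch_size must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(list(hidden_units = hidden_units, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = seed),
            class = "gan_config")
}

#' Train a generator on the expression profiles of one stage
#'
#' Adversarial training of a generator (m -> hidden -> m, ReLU hidden, linear
#' output) against a discriminator (m -> hidden -> 1, LeakyReLU(0.2) hidden,
#' sigmoid output) with the non-saturating binary-cross-entropy objective and
#' Adam. Expression is standardised per gene before training and generated
#' samples are mapped back to the original scale. Latent vectors are drawn
#' per gene from Normal(mean, SD) of the training data; those moments are
#' stored on the returned object and reused at generation time.
#'
#' @param x numeric matrix of training expression for a single stage
#'   (samples x genes), at least 2 rows, finite values.
#' @param config a [gan_config()].
#' @param stage optional stage label (1-4) recorded on the result.
#' @return An object of class `trained_generator` with elements `generator`,
#'   `discriminator`, `latent` (per-gene `mean`, `sd`), `scaler`, `stage`,
#'   `loss_trace` (per-epoch generator/discriminator loss), `config`.
#' @export
fit_stage_gan <- function(x, config = gan_config(), stage = NA_integer_) {
  x <- as.matrix(x)
  assert_that(all(is.finite(x)), "non-finite values in training expression")
  if (nrow(x) < 2) {
    stop("a stage with a single sample cannot train a GAN; pool stages or ",
         "skip augmentation for it", call. = FALSE)
  }
  m <- ncol(x)
  latent <- list(mean = colMeans(x), sd = col_sds(x))
  scaler <- scaler_fit(x)
  xs <- scaler_apply(scaler, x)
  n <- nrow(x)
  bs <- config$batch_size
  if (bs > n) {
    warning(sprintf("batch_size %d clamped to stage sample count %d", bs, n))
    bs <- n
  }

  with_seed(derive_seed(config$seed, 7919, stage), {
    G <- gan_generator_init(m, config$hidden_units)
    D <- mlp_new(c(m, config$hidden_units, 1), c("lrelu", "sigmoid"))
    sG <- adam_new(G)
    sD <- adam_new(D)
    lr <- config$learning_rate
    beta1 <- 0.5  # standard choice for adversarial Adam
    d_trace <- g_trace <- numeric(config$epochs)
    eps <- 1e-12

    draw_latent <- function(k) {
      z <- matrix(stats::rnorm(k * m, mean = rep(latent$mean, each = k),
                               sd = rep(latent$sd, each = k)), k, m)
      scaler_apply(scaler, z)
    }

    for (e in seq_len(config$epochs)) {
      ord <- sample.int(n)
      d_loss <- g_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        k <- length(idx)
        real <- xs[idx, , drop = FALSE]

        # --- discriminator step: real labelled 0.9 (one-sided label
        # smoothing, keeps D from saturating on very small stages), fake 0
        fake <- mlp_forward(G, draw_latent(k))$out
        Xd <- rbind(real, fake)
        y <- c(rep(0.9, k), rep(0, k))
        cd <- mlp_forward(D, Xd)
        p <- pmin(pmax(cd$out[, 1], eps), 1 - eps)
        d_loss <- d_loss - mean(y * log(p) + (1 - y) * log(1 - p))
        bkd <- mlp_backward(D, cd, matrix((cd$out[, 1] - y) / (2 * k), ncol = 1))
        upd <- adam_step(D, sD, bkd$grads, lr, beta1)
        D <- upd$net; sD <- upd$state

        # --- generator step (non-saturating): push D(fake) toward 1
        cg <- mlp_forward(G, draw_latent(k))
        cd2 <- mlp_forward(D, cg$out)
        p2 <- pmin(pmax(cd2$out[, 1], eps), 1 - eps)
        g_loss <- g_loss - mean(log(p2))
        bk_through_d <- mlp_backward(D, cd2,
                                     matrix((cd2$out[, 1] - 1) / k, ncol = 1))
        bkg <- mlp_backward(G, cg, bk_through_d$dinput)
        upd <- adam_step(G, sG, bkg$grads, lr, beta1)
        G <- upd$net; sG <- upd$state
        nb <- nb + 1
      }
      d_trace[e] <- d_loss / nb
      g_trace[e] <- g_loss / nb
    }

    structure(list(generator = G, discriminator = D, latent = latent,
                   scaler = scaler, stage = stage, n_train = n,
                   loss_trace = data.frame(epoch = seq_len(config$epochs),
                                           d_loss = d_trace, g_loss = g_trace),
                   config = config),
              class = "trained_generator")
  })
}

#' @export
print.trained_generator <- function(x, ...) {
  cat(sprintf(
    "trained_generator (stage %s): %d genes, %d hidden units, %d epochs\n",
    format(x$stage), length(x$latent$mean), x$config$hidden_units,
    x$config$epochs))
  invisible(x)
}

#' Draw synthetic expression samples from a trained generator
#'
#' Samples `count` latent vectors from the stored per-gene Normal(mean, SD),
#' maps them through the generator and inverts the training standardisation.
#'
#' @param gen a [fit_stage_gan()] result.
#' @param count number of samples to generate (>= 1).
#' @param seed integer seed (defaults to the training seed).
#' @return matrix of `count` rows and one column per gene.
#' @export
sample_generator <- function(gen, count, seed = gen$config$seed) {
  assert_that(is_count(count), "count must be a positive integer")
  m <- length(gen$latent$mean)
  with_seed(derive_seed(seed, 15485863, gen$stage), {
    z <- matrix(stats::rnorm(count * m,
                             mean = rep(gen$latent$mean, each = count),
                             sd = rep(gen$latent$sd, each = count)),
                count, m)
    out <- mlp_forward(gen$generator, scaler_apply(gen$scaler, z))$out
    out <- scaler_invert(gen$scaler, out)
    colnames(out) <- names(gen$latent$mean)
    out
  })
}

#' Held-out real-versus-fake discriminator accuracy
#'
#' Equilibrium diagnostic: at convergence the discriminator should be close to
#' chance (accuracy well inside (0.3, 0.7)) on data it has not trained on.
#'
#' @param gen a [fit_stage_gan()] result.
#' @param x_real held-out real expression matrix for the generator's stage.
#' @param seed seed for the fake draw.
#' @return proportion of correct real/fake calls at threshold 0.5.
#' @export
discriminator_accuracy <- function(gen, x_real, seed = gen$config$seed + 1) {
  x_real <- as.matrix(x_real)
  fake <- sample_generator(gen, nrow(x_real), seed = seed)
  xs <- scaler_apply(gen$scaler, rbind(x_real, fake))
  p <- mlp_forward(gen$discriminator, xs)$out[, 1]
  truth <- c(rep(1, nrow(x_real)), rep(0, nrow(x_real)))
  mean((p > 0.5) == truth)
}

# Generator initialised near the identity map: because the latent vector
# already follows the per-gene training distribution, relu(z) - relu(-z) = z
# realised on paired hidden units makes the untrained generator emit the
# latent approximation of the stage distribution, which adversarial training
# then refines (it only has to learn corrections, e.g. gene-gene structure,
# not the marginals from scratch). Small-noise entries break symmetry. Genes
# beyond floor(hidden/2) paired channels fall back to He initialisation.
gan_generator_init <- function(m, hidden) {
  G <- mlp_new(c(m, hidden, m), c("relu", "linear"))
  k <- min(m, floor(hidden / 2))
  if (k >= 1) {
    noise <- 0.01
    W1 <- matrix(stats::rnorm(m * hidden, sd = noise), m, hidden)
    W2 <- matrix(stats::rnorm(hidden * m, sd = noise), hidden, m)
    for (g in seq_len(k)) {
      W1[g, 2 * g - 1] <- 1
      W1[g, 2 * g] <- -1
      W2[2 * g - 1, g] <- 1
      W2[2 * g, g] <- -1
    }
    if (m > k) {  # remaining genes keep He-scaled columns
      W1[(k + 1):m, ] <- G$layers[[1]]$W[(k + 1):m, ]
    }
    G$layers[[1]]$W <- W1
    G$layers[[2]]$W <- W2
  }
  G
}

# Container shared by all augmenters.
augmented_training_set <- function(expression, stages, method,
                                   fold = NA_integer_) {
  structure(list(expression = expression, stages = as.integer(stages),
                 method = method, fold = fold),
            class = "augmented_training_set")
}

#' @export
print.augmented_training_set <- function(x, ...) {
  cat(sprintf("augmented_training_set (%s%s): %d samples x %d genes\n",
              x$method, if (is.na(x$fold)) "" else paste0(", fold ", x$fold),
              nrow(x$expression), ncol(x$expression)))
  cat("stage counts:", paste(sprintf("%s=%d", names(table(x$stages)),
                                     table(x$stages)), collapse = " "), "\n")
  invisible(x)
}

#' GAN augmentation of a training split, stage ratios preserved
#'
#' Fits one independent GAN per stage on the stage's training expression and
#' generates exactly `fold` times that stage's training count, so the stage
#' ratio of the augmented set equals the training ratio by construction.
#' The augmented set contains synthetic samples only; it replaces the original
#' training data for classifier fitting.
#'
#' @param split a [stratified_split()] result (augmenters only read
#'   `split$train`).
#' @param fold integer multiplier (1, 5, 20 and 100 are the GANk variants).
#' @param config a [gan_config()].
#' @return an `augmented_training_set` with `fold * n_s` samples per stage s.
#' @export
augment_gan <- function(split, fold, config = gan_config()) {
  assert_that(is_count(fold), "fold must be a positive integer")
  train <- split$train
  stages <- sort(unique(train$stages))
  gens <- lapply(stages, function(s) {
    fit_stage_gan(train$expression[train$stages == s, , drop = FALSE],
                  config, stage = s)
  })
  pieces <- lapply(gens, function(g) {
    n_s <- g$n_train
    sample_generator(g, fold * n_s)
  })
  expr <- do.call(rbind, pieces)
  labels <- rep(stages, vapply(pieces, nrow, integer(1)))
  rownames(expr) <- sprintf("GAN%d_%05d", fold, seq_len(nrow(expr)))
  out <- augmented_training_set(expr, labels, "GAN", fold)
  out$generators <- gens
  out
}
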