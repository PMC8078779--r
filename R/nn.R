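# Minimal dense-network machinery (forward/backward + Adam) shared by the
# GAN, the denoising autoencoder and the DNN classifier. All randomness comes
# from R's RNG so every fit is exactly reproducible under a seed.
#
# Conventions: data matrices are n x d; layer i maps A %*% W + b. The backward
# pass takes the loss gradient w.r.t. the LAST layer's pre-activation (for
# softmax + cross-entropy and sigmoid + BCE this is (p - y)/n, which avoids
# numerically unstable intermediate terms).

mlp_new <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1)
  layers <- vector("list", length(acts))
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    sd <- sqrt(2 / fan_in)  # He initialisation, suits ReLU-family hidden units
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sd),
                 fan_in, sizes[i + 1]),
      b = rep(0, sizes[i + 1]),
      act = acts[i]
    )
  }
  list(layers = layers)
}

act_apply <- function(act, z) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         lrelu = ifelse(z > 0, z, 0.2 * z),
         sigmoid = 1 / (1 + exp(-z)),
         softmax = {
           e <- exp(z - apply(z, 1, max))
           e / rowSums(e)
         },
         stop("unknown activation: ", act))
}

# derivative w.r.t. pre-activation, given pre (z); only used for hidden layers
act_grad <- function(act, z) {
  switch(act,
         linear = matrix(1, nrow(z), ncol(z)),
         relu = (z > 0) * 1,
         lrelu = ifelse(z > 0, 1, 0.2),
         stop("act_grad only supports hidden activations, got: ", act))
}

mlp_forward <- function(net, X) {
  L <- length(net$layers)
  pre <- post <- vector("list", L)
  a <- X
  for (i in seq_len(L)) {
    ly <- net$layers[[i]]
    z <- a %*% ly$W + rep(ly$b, each = nrow(a))
    a <- act_apply(ly$act, z)
    pre[[i]] <- z
    post[[i]] <- a
  }
  list(out = a, pre = pre, post = post, input = X)
}

# dpre_last: dLoss/d(pre-activation of final layer). Returns per-layer grads
# and the gradient w.r.t. the network input (needed to backprop the generator
# through the discriminator).
mlp_backward <- function(net, cache, dpre_last) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dpre_last
  for (i in rev(seq_len(L))) {
    a_prev <- if (i == 1) cache$input else cache$post[[i - 1]]
    grads[[i]] <- list(dW = crossprod(a_prev, delta), db = colSums(delta))
    dA_prev <- tcrossprod(delta, net$layers[[i]]$W)
    if (i > 1) {
      delta <- dA_prev * act_grad(net$layers[[i - 1]]$act, cache$pre[[i - 1]])
    } else {
      dinput <- dA_prev
    }
  }
  list(grads = grads, dinput = dinput)
}

adam_new <- function(net) {
  list(t = 0, m = lapply(net$layers, function(ly) {
    list(W = ly$W * 0, b = ly$b * 0)
  }), v = lapply(net$layers, function(ly) {
    list(W = ly$W * 0, b = ly$b * 0)
  }))
}

adam_step <- function(net, state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[paste0("d", p)]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      step <- lr * (state$m[[i]][[p]] / bc1) /
        (sqrt(state$v[[i]][[p]] / bc2) + eps)
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - step
    }
  }
  list(net = net, state = state)
}

# Per-gene standardisation used before network training; sd 0 maps to 1 so
# constant genes pass through as zeros and are restored exactly on inversion.
scaler_fit <- function(x) {
  mu <- colMeans(x)
  sd <- col_sds(x)
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}
scaler_apply <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}
scaler_invert <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

# Generic minibatch trainer for supervised dense nets (DNN classifier, DAE).
# loss_grad(out, Yb) must return list(loss = scalar, dpre = matrix).
mlp_train <- function(net, X, Y, epochs, batch_size, lr, loss_grad) {
  state <- adam_new(net)
  n <- nrow(X)
  bs <- min(batch_size, n)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      cache <- mlp_forward(net, X[idx, , drop = FALSE])
      lg <- loss_grad(cache$out, Y[idx, , drop = FALSE])
      bk <- mlp_backward(net, cache, lg$dpre)
      upd <- adam_step(net, state, bk$grads, lr)
      net <- upd$net
      state <- upd$state
      total <- total + lg$loss * length(idx)
    }
    trace[e] <- total / n
  }
  list(net = net, trace = trace)
}
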