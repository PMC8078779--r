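# 1-D convolution machinery for the CNN classifier. Feature maps are 3-D
# arrays (n samples, length, channels); convolutions use valid padding and an
# im2col lowering so each layer is a single matrix product. Max-pooling keeps
# a trailing partial window (ceil mode), which makes the minimum usable input
# length for the default architecture 13 genes.

conv1d_forward <- function(x3, W, b, k) {
  n <- dim(x3)[1]; L <- dim(x3)[2]; cin <- dim(x3)[3]
  lout <- L - k + 1
  cols <- array(0, c(n, lout, k * cin))
  for (dk in seq_len(k)) {
    cols[, , (seq_len(cin) - 1) * k + dk] <-
      x3[, dk:(dk + lout - 1), , drop = FALSE]
  }
  cols_m <- cols
  dim(cols_m) <- c(n * lout, k * cin)
  z <- cols_m %*% W + rep(b, each = n * lout)
  dim(z) <- c(n, lout, length(b))
  list(z = z, cols = cols_m)
}

conv1d_backward <- function(dz, cache, W, k, cin, L) {
  n <- dim(dz)[1]; lout <- dim(dz)[2]; cout <- dim(dz)[3]
  dz_m <- dz
  dim(dz_m) <- c(n * lout, cout)
  dW <- crossprod(cache$cols, dz_m)
  db <- colSums(dz_m)
  dcols <- tcrossprod(dz_m, W)
  dim(dcols) <- c(n, lout, k * cin)
  dx <- array(0, c(n, L, cin))
  for (dk in seq_len(k)) {
    dx[, dk:(dk + lout - 1), ] <- dx[, dk:(dk + lout - 1), , drop = FALSE] +
      dcols[, , (seq_len(cin) - 1) * k + dk, drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

# ceil-mode max pool, window = stride = p (p = 2 in the default architecture);
# ties and the trailing singleton window route gradients to the earlier slot.
pool_forward <- function(x3, p = 2) {
  L <- dim(x3)[2]
  a_idx <- seq(1, L, by = p)
  out <- x3[, a_idx, , drop = FALSE]
  take <- array(1L, dim(out))  # offset within window that holds the max
  for (off in seq_len(p - 1)) {
    b_idx <- a_idx + off
    ok <- b_idx <= L
    if (!any(ok)) break
    cand <- x3[, b_idx[ok], , drop = FALSE]
    cur <- out[, ok, , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    out[, ok, ] <- cur
    tk <- take[, ok, , drop = FALSE]
    tk[better] <- off + 1L
    take[, ok, ] <- tk
  }
  list(out = out, take = take, a_idx = a_idx, L = L)
}

pool_backward <- function(dout, cache, x3_dims) {
  dx <- array(0, x3_dims)
  L <- x3_dims[2]
  for (off in sort(unique(as.vector(cache$take)))) {
    idx <- cache$a_idx + (off - 1L)
    ok <- idx <= L
    g <- dout * (cache$take == off)
    dx[, idx[ok], ] <- dx[, idx[ok], , drop = FALSE] + g[, ok, , drop = FALSE]
  }
  dx
}

cnn_dims <- function(m, k, p) {
  l1 <- m - k + 1
  p1 <- if (l1 >= 1) ceiling(l1 / p) else 0
  l2 <- p1 - k + 1
  p2 <- if (l2 >= 1) ceiling(l2 / p) else 0
  list(l1 = l1, p1 = p1, l2 = l2, p2 = p2)
}

cnn_min_features <- function(k, p) {
  m <- k
  while (cnn_dims(m, k, p)$p2 < 1) m <- m + 1
  m
}

cnn_new <- function(m, config) {
  k <- config$kernel_size
  f <- config$filters
  dims <- cnn_dims(m, k, config$pool_size)
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  flat <- dims$p2 * f[2]
  list(layers = list(
    list(W = he(k, k, f[1]), b = rep(0, f[1])),
    list(W = he(k * f[1], k * f[1], f[2]), b = rep(0, f[2])),
    list(W = he(flat, flat, config$dense_units), b = rep(0, config$dense_units)),
    list(W = he(config$dense_units, config$dense_units, 4), b = rep(0, 4))
  ), dims = dims, m = m, k = k, p = config$pool_size, filters = f)
}

cnn_forward <- function(net, X) {
  n <- nrow(X)
  k <- net$k; p <- net$p
  x0 <- array(X, c(n, net$m, 1))
  c1 <- conv1d_forward(x0, net$layers[[1]]$W, net$layers[[1]]$b, k)
  a1 <- pmax(c1$z, 0)
  pl1 <- pool_forward(a1, p)
  c2 <- conv1d_forward(pl1$out, net$layers[[2]]$W, net$layers[[2]]$b, k)
  a2 <- pmax(c2$z, 0)
  pl2 <- pool_forward(a2, p)
  flat <- pl2$out
  dim(flat) <- c(n, prod(dim(pl2$out)[2:3]))
  z3 <- flat %*% net$layers[[3]]$W + rep(net$layers[[3]]$b, each = n)
  a3 <- pmax(z3, 0)
  z4 <- a3 %*% net$layers[[4]]$W + rep(net$layers[[4]]$b, each = n)
  probs <- act_apply("softmax", z4)
  list(probs = probs, x0 = x0, c1 = c1, a1 = a1, pl1 = pl1, c2 = c2, a2 = a2,
       pl2 = pl2, flat = flat, z3 = z3, a3 = a3)
}

cnn_backward <- function(net, cache, dpre4) {
  n <- nrow(dpre4)
  g4 <- list(dW = crossprod(cache$a3, dpre4), db = colSums(dpre4))
  da3 <- tcrossprod(dpre4, net$layers[[4]]$W)
  dz3 <- da3 * (cache$z3 > 0)
  g3 <- list(dW = crossprod(cache$flat, dz3), db = colSums(dz3))
  dflat <- tcrossprod(dz3, net$layers[[3]]$W)
  dpool2 <- dflat
  dim(dpool2) <- dim(cache$pl2$out)
  da2 <- pool_backward(dpool2, cache$pl2, dim(cache$a2))
  dz2 <- da2 * (cache$c2$z > 0)
  cb2 <- conv1d_backward(dz2, cache$c2, net$layers[[2]]$W, net$k,
                         net$filters[1], dim(cache$pl1$out)[2])
  g2 <- list(dW = cb2$dW, db = cb2$db)
  da1 <- pool_backward(cb2$dx, cache$pl1, dim(cache$a1))
  dz1 <- da1 * (cache$c1$z > 0)
  cb1 <- conv1d_backward(dz1, cache$c1, net$layers[[1]]$W, net$k, 1, net$m)
  g1 <- list(dW = cb1$dW, db = cb1$db)
  list(g1, g2, g3, g4)
}

cnn_train <- function(net, X, Y, epochs, batch_size, lr) {
  state <- adam_new(net)
  n <- nrow(X)
  bs <- min(batch_size, n)
  trace <- numeric(epochs)
  eps <- 1e-12
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      cache <- cnn_forward(net, X[idx, , drop = FALSE])
      Yb <- Y[idx, , drop = FALSE]
      total <- total - sum(log(pmax(rowSums(cache$probs * Yb), eps)))
      dpre <- (cache$probs - Yb) / length(idx)
      grads <- cnn_backward(net, cache, dpre)
      upd <- adam_step(net, state, grads, lr)
      net$layers <- upd$net$layers
      state <- upd$state
    }
    trace[e] <- total / n
  }
  list(net = net, trace = trace)
}
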