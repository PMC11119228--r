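# Minimal dense/convolutional neural-network primitives in vectorised base
# R. Images are arrays [h, w, c, batch]; convolutions are im2col matrix
# products with precomputed gather indices; gradients are exact analytic
# backprop (checked against finite differences in the test suite).

# Gather indices mapping each (output position, kernel offset x channel)
# pair to a linear index into the zero-padded input volume [hp, wp, cin].
im2col_index <- function(h, w, cin, k, stride, pad) {
  hp <- h + 2 * pad; wp <- w + 2 * pad
  ho <- (hp - k) %/% stride + 1
  wo <- (wp - k) %/% stride + 1
  oi <- rep(seq_len(ho) - 1L, times = wo)
  oj <- rep(seq_len(wo) - 1L, each = ho)       # positions column-major in [ho, wo]
  ki <- rep(seq_len(k) - 1L, times = k * cin)
  kj <- rep(rep(seq_len(k) - 1L, each = k), times = cin)
  kc <- rep(seq_len(cin) - 1L, each = k * k)
  P <- ho * wo; K <- k * k * cin
  rows <- outer(oi * stride, ki, "+") + 1L     # P x K
  cols <- outer(oj * stride, kj, "+") + 1L
  chan <- matrix(kc, P, K, byrow = TRUE)
  idx <- rows + (cols - 1L) * hp + chan * (hp * wp)
  list(idx = idx, ho = ho, wo = wo, P = P, K = K, hp = hp, wp = wp)
}

pad_batch <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

conv_layer_new <- function(h, w, cin, cout, k = 3, stride = 2, pad = 1,
                           activation = "relu") {
  K <- k * k * cin
  W <- matrix(stats::rnorm(K * cout, sd = sqrt(2 / K)), K, cout)
  g <- im2col_index(h, w, cin, k, stride, pad)
  list(type = "conv", W = W, b = numeric(cout), k = k, stride = stride,
       pad = pad, h = h, w = w, cin = cin, cout = cout, gather = g,
       activation = activation)
}

conv_forward <- function(layer, x, keep_cache = TRUE) {
  g <- layer$gather
  B <- dim(x)[4]
  xp <- pad_batch(x, layer$pad)
  xm <- matrix(xp, g$hp * g$wp * layer$cin, B)
  cols <- xm[as.vector(g$idx), , drop = FALSE]       # (P*K) x B
  dim(cols) <- c(g$P, g$K, B)
  M <- aperm(cols, c(1, 3, 2))
  dim(M) <- c(g$P * B, g$K)
  Y <- M %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  mask <- NULL
  if (layer$activation == "relu") {
    mask <- Y > 0
    Y <- Y * mask
  }
  out <- array(Y, c(g$P, B, layer$cout))
  out <- aperm(out, c(1, 3, 2))
  dim(out) <- c(g$ho, g$wo, layer$cout, B)
  cache <- if (keep_cache) list(M = M, mask = mask, B = B) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(layer, cache, dout, need_dx = TRUE) {
  g <- layer$gather
  B <- cache$B
  dY <- dout
  dim(dY) <- c(g$P, layer$cout, B)
  dY <- aperm(dY, c(1, 3, 2))
  dim(dY) <- c(g$P * B, layer$cout)
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  grad <- list(W = crossprod(cache$M, dY), b = colSums(dY))
  dx <- NULL
  if (need_dx) {
    dM <- dY %*% t(layer$W)                     # (P*B) x K
    dim(dM) <- c(g$P, B, g$K)
    dM <- aperm(dM, c(1, 3, 2))                 # (P, K, B)
    npix <- g$hp * g$wp * layer$cin
    idx_all <- rep(as.vector(g$idx), times = B) +
      rep((seq_len(B) - 1L) * npix, each = g$P * g$K)
    acc <- rowsum(as.vector(dM), idx_all)
    dxp <- numeric(npix * B)
    dxp[as.integer(rownames(acc))] <- acc[, 1]
    dim(dxp) <- c(g$hp, g$wp, layer$cin, B)
    p <- layer$pad
    dx <- dxp[p + seq_len(layer$h), p + seq_len(layer$w), , , drop = FALSE]
  }
  list(grad = grad, dx = dx)
}

dense_layer_new <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(1 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

dense_forward <- function(layer, x) sweep(x %*% layer$W, 2, layer$b, "+")

dense_backward <- function(layer, x, dout) {
  list(grad = list(W = crossprod(x, dout), b = colSums(dout)),
       dx = dout %*% t(layer$W))
}

# Global average pooling [h, w, c, B] -> B x c
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  cm <- colMeans(m)
  dim(cm) <- c(d[3], d[4])
  t(cm)
}

gap_backward <- function(dout, dims) {
  # dout: B x c -> spread evenly over h*w positions
  h <- dims[1]; w <- dims[2]; cc <- dims[3]; B <- dims[4]
  dx <- array(0, dims)
  scale <- 1 / (h * w)
  per <- t(dout) * scale                        # c x B
  dx_flat <- array(rep(as.vector(per), each = h * w), c(h * w, cc, B))
  dim(dx_flat) <- c(h, w, cc, B)
  dx_flat
}

# Global max pooling [h, w, c, B] -> B x c. Max pooling keeps the response
# of a focal texture that covers only part of the receptive field, where
# average pooling would dilute it.
gmp_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")   # argmax per (c, b) column
  val <- m[cbind(idx, seq_along(idx))]
  out <- matrix(val, d[3], d[4])
  list(out = t(out), idx = idx)
}

gmp_backward <- function(dout, idx, dims) {
  h <- dims[1]; w <- dims[2]; cc <- dims[3]; B <- dims[4]
  m <- matrix(0, h * w, cc * B)
  m[cbind(idx, seq_along(idx))] <- as.vector(t(dout))
  dim(m) <- dims
  m
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- Adam optimiser ------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) p * 0)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = zeros, v = zeros, t = 0)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Flatten fe layer parameters into a named list for the optimiser.
fe_params <- function(fe) {
  out <- list()
  for (i in seq_along(fe$conv)) {
    out[[paste0("c", i, "W")]] <- fe$conv[[i]]$W
    out[[paste0("c", i, "b")]] <- fe$conv[[i]]$b
  }
  out$dW <- fe$dense$W
  out$db <- fe$dense$b
  out
}

fe_set_params <- function(fe, params) {
  for (i in seq_along(fe$conv)) {
    fe$conv[[i]]$W <- params[[paste0("c", i, "W")]]
    fe$conv[[i]]$b <- params[[paste0("c", i, "b")]]
  }
  fe$dense$W <- params$dW
  fe$dense$b <- params$db
  fe
}
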