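# Minimal dense/convolutional network primitives on base R arrays.
# Activations are stored as (N, H, W, C) arrays; convolutions are realized
# as a compiled im2col gather (src/conv_ops.cpp) + one BLAS matrix
# multiply, which is where essentially all the training time goes. Only
# 3x3 kernels with stride 1 are supported (the architecture is fixed);
# pooling is valid/floor max pooling.

conv_forward <- function(x, Wm, b, padding) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (padding == "same") {
    xp <- array(0, c(N, H + 2L, W + 2L, C))
    xp[, 2:(H + 1), 2:(W + 1), ] <- x
    Ho <- H; Wo <- W
  } else {
    xp <- x; Ho <- H - 2L; Wo <- W - 2L
  }
  dp <- dim(xp)
  cols <- .im2col3(xp, dp[1], dp[2], dp[3], dp[4], Ho, Wo)
  out <- cols %*% Wm
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(N, Ho, Wo, ncol(Wm))
  list(out = out, cols = cols, in_dim = d, out_dim = dim(out), padding = padding)
}

conv_backward <- function(dout, cache, Wm) {
  od <- cache$out_dim; N <- od[1]; Ho <- od[2]; Wo <- od[3]; Cout <- od[4]
  dmat <- dout
  dim(dmat) <- c(N * Ho * Wo, Cout)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wm)
  din <- cache$in_dim; H <- din[2]; W <- din[3]; C <- din[4]
  if (cache$padding == "same") {
    dxp <- .col2im3(dcols, N, H + 2L, W + 2L, C, Ho, Wo)
    dim(dxp) <- c(N, H + 2L, W + 2L, C)
    dx <- dxp[, 2:(H + 1), 2:(W + 1), , drop = FALSE]
  } else {
    dx <- .col2im3(dcols, N, H, W, C, Ho, Wo)
    dim(dx) <- din
  }
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x, pool) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- pool[1]; pw <- pool[2]
  res <- .maxpool_fwd(x, N, H, W, C, ph, pw)
  out <- res$out
  dim(out) <- c(N, H %/% ph, W %/% pw, C)
  list(out = out, argmax = res$argmax, in_dim = d, pool = pool, out_dim = dim(out))
}

maxpool_backward <- function(dout, cache) {
  dx <- .maxpool_bwd(dout, cache$argmax, prod(cache$in_dim))
  dim(dx) <- cache$in_dim
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
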