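# Minimal vectorised neural-network primitives.
#
# Batch tensors are plain R arrays with dim c(H, W, C, N). Convolutions are
# evaluated as one GEMM per kernel offset (k*k GEMMs of (H*W*N) x C_in by
# C_in x C_out), which keeps everything inside BLAS; backward passes mirror
# the same decomposition. No autograd: the model graph in model.R chains
# these primitives explicitly.

he_init <- function(dims, fan_in, seed) {
  with_seed(seed, array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims))
}

layer_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L, seed = 1L) {
  list(kind = "conv",
       W = he_init(c(kernel, kernel, in_ch, out_ch), kernel * kernel * in_ch, seed),
       b = numeric(out_ch),
       kernel = as.integer(kernel), stride = as.integer(stride), pad = as.integer(pad))
}

layer_relu <- function() list(kind = "relu")

## fixed nearest-neighbour resize, expressed as a 0/1 operator on the
## vectorised spatial grid so forward and backward are single GEMMs
layer_resize <- function(from, to) {
  sel <- function(n_to, n_from) {
    src <- pmin(pmax(floor(((seq_len(n_to) - 0.5) * n_from) / n_to) + 1, 1), n_from)
    A <- matrix(0, n_to, n_from)
    A[cbind(seq_len(n_to), src)] <- 1
    A
  }
  A <- sel(to[1], from[1])
  B <- sel(to[2], from[2])
  list(kind = "resize", R = kronecker(B, A), from = from, to = to)
}

conv_out_side <- function(side, kernel, stride, pad) {
  (side + 2L * pad - kernel) %/% stride + 1L
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  Ho <- conv_out_side(H, k, s, p); Wo <- conv_out_side(W, k, s, p)
  Cout <- dim(layer$W)[4]
  if (p > 0) {
    xp <- array(0, c(H + 2 * p, W + 2 * p, C, N))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else xp <- x
  i0 <- seq(1L, by = s, length.out = Ho)
  j0 <- seq(1L, by = s, length.out = Wo)
  Y <- matrix(layer$b, Ho * Wo * N, Cout, byrow = TRUE)
  for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
    Xs <- xp[i0 + di, j0 + dj, , , drop = FALSE]
    M <- matrix(aperm(Xs, c(1, 2, 4, 3)), Ho * Wo * N, C)
    Y <- Y + M %*% matrix(layer$W[di + 1, dj + 1, , ], C, Cout)
  }
  aperm(array(Y, c(Ho, Wo, N, Cout)), c(1, 2, 4, 3))
}

conv_backward <- function(layer, x, dout) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  do_ <- dim(dout)
  Ho <- do_[1]; Wo <- do_[2]; Cout <- do_[3]
  if (p > 0) {
    xp <- array(0, c(H + 2 * p, W + 2 * p, C, N))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else xp <- x
  i0 <- seq(1L, by = s, length.out = Ho)
  j0 <- seq(1L, by = s, length.out = Wo)
  dY <- matrix(aperm(dout, c(1, 2, 4, 3)), Ho * Wo * N, Cout)
  dW <- array(0, dim(layer$W))
  dxp <- array(0, dim(xp))
  for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
    Xs <- xp[i0 + di, j0 + dj, , , drop = FALSE]
    M <- matrix(aperm(Xs, c(1, 2, 4, 3)), Ho * Wo * N, C)
    dW[di + 1, dj + 1, , ] <- crossprod(M, dY)
    dXs <- dY %*% t(matrix(layer$W[di + 1, dj + 1, , ], C, Cout))
    dXs <- aperm(array(dXs, c(Ho, Wo, N, C)), c(1, 2, 4, 3))
    dxp[i0 + di, j0 + dj, , ] <- dxp[i0 + di, j0 + dj, , ] + dXs
  }
  dx <- if (p > 0) dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dW, b = colSums(dY)))
}

resize_forward <- function(layer, x) {
  d <- dim(x)
  Y <- layer$R %*% matrix(x, d[1] * d[2], d[3] * d[4])
  array(Y, c(layer$to[1], layer$to[2], d[3], d[4]))
}

resize_backward <- function(layer, x, dout) {
  d <- dim(x)
  dX <- crossprod(layer$R, matrix(dout, prod(layer$to), d[3] * d[4]))
  list(dx = array(dX, d), grads = NULL)
}

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    caches[[i]] <- x
    l <- layers[[i]]
    x <- switch(l$kind,
      conv = conv_forward(l, x),
      relu = pmax(x, 0),
      resize = resize_forward(l, x))
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      bk <- conv_backward(l, caches[[i]], dout)
      dout <- bk$dx
      grads[[i]] <- bk$grads
    } else if (l$kind == "relu") {
      dout <- dout * (caches[[i]] > 0)
    } else if (l$kind == "resize") {
      dout <- resize_backward(l, caches[[i]], dout)$dx
    }
  }
  list(dx = dout, grads = grads)
}

## two-layer perceptron head: linear -> relu -> linear
mlp_init <- function(d_in, hidden, d_out, seed) {
  list(W1 = he_init(c(d_in, hidden), d_in, seed),
       b1 = numeric(hidden),
       W2 = he_init(c(hidden, d_out), hidden, seed + 1L),
       b2 = numeric(d_out))
}

mlp_forward <- function(fc, x) {
  h_pre <- sweep(x %*% fc$W1, 2, fc$b1, "+")
  h <- pmax(h_pre, 0)
  logits <- sweep(h %*% fc$W2, 2, fc$b2, "+")
  list(logits = logits, h = h, x = x)
}

mlp_backward <- function(fc, cache, dlogits) {
  dW2 <- crossprod(cache$h, dlogits)
  db2 <- colSums(dlogits)
  dh <- dlogits %*% t(fc$W2)
  dh <- dh * (cache$h > 0)
  dW1 <- crossprod(cache$x, dh)
  db1 <- colSums(dh)
  dx <- dh %*% t(fc$W1)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## numerically stable softmax cross-entropy; targets are 1-based class ids
softmax_ce <- function(logits, targets) {
  n <- nrow(logits)
  shifted <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(shifted)))
  loss <- mean(lse - shifted[cbind(seq_len(n), targets)])
  probs <- exp(shifted - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(n), targets)] <- dlogits[cbind(seq_len(n), targets)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

## Adam with in-place state threaded through an environment
adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

adam_update <- function(state, key, param, grad, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- state$m[[key]]
  v <- state$v[[key]]
  if (is.null(m)) { m <- param * 0; v <- param * 0 }
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad * grad
  state$m[[key]] <- m
  state$v[[key]] <- v
  mh <- m / (1 - beta1^state$t)
  vh <- v / (1 - beta2^state$t)
  param - lr * mh / (sqrt(vh) + eps)
}
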