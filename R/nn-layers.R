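# Vectorized layer primitives with explicit forward caches and backward
# passes. Batch layouts: 1-D signals N x L x C, 2-D maps N x H x W x C,
# dense activations N x D. Convolutions use 'same' zero padding (left pad
# floor((k-1)/2)) so the published pooling arithmetic holds exactly.
# Gradient correctness is pinned by finite-difference tests.

conv1d_fwd <- function(x, W, b) {
  list(out = conv1d_fw_cpp(x, W, as.numeric(b)),
       cache = list(x = x, W = W))
}

conv1d_bwd <- function(cache, dout) {
  conv1d_bw_cpp(cache$x, cache$W, dout)
}

conv2d_fwd <- function(x, W, b) {
  list(out = conv2d_fw_cpp(x, W, as.numeric(b)),
       cache = list(x = x, W = W))
}

conv2d_bwd <- function(cache, dout) {
  conv2d_bw_cpp(cache$x, cache$W, dout)
}

# Pure-R reference convolutions: the independent oracle the compiled kernels
# are checked against in the test suite.
conv1d_fwd_ref <- function(x, W, b) {
  d <- dim(x); N <- d[1]; L <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  pad_l <- (k - 1L) %/% 2L
  xp <- array(0, c(N, L + k - 1L, Cin))
  xp[, pad_l + seq_len(L), ] <- x
  out <- matrix(rep(b, each = N * L), N * L, Cout)
  for (j in seq_len(k)) {
    Xj <- matrix(xp[, j:(j + L - 1L), , drop = FALSE], N * L, Cin)
    out <- out + Xj %*% matrix(W[j, , ], Cin, Cout)
  }
  array(out, c(N, L, Cout))
}

conv2d_fwd_ref <- function(x, W, b) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(N, H + kh - 1L, Wd + kw - 1L, Cin))
  xp[, ph + seq_len(H), pw + seq_len(Wd), ] <- x
  out <- matrix(rep(b, each = N * H * Wd), N * H * Wd, Cout)
  for (a in seq_len(kh)) for (bb in seq_len(kw)) {
    Xab <- matrix(xp[, a:(a + H - 1L), bb:(bb + Wd - 1L), , drop = FALSE],
                  N * H * Wd, Cin)
    out <- out + Xab %*% matrix(W[a, bb, , ], Cin, Cout)
  }
  array(out, c(N, H, Wd, Cout))
}

maxpool1d_fwd <- function(x, pool, stride) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  Lo <- (L - pool) %/% stride + 1L
  m <- array(-Inf, c(N, Lo, C)); arg <- array(0L, c(N, Lo, C))
  for (p in seq_len(pool)) {
    cols <- seq(p, by = stride, length.out = Lo)
    cand <- x[, cols, , drop = FALSE]
    upd <- cand > m
    m[upd] <- cand[upd]; arg[upd] <- p
  }
  list(out = m, cache = list(arg = arg, L = L, pool = pool, stride = stride,
                             N = N, C = C, Lo = Lo))
}

maxpool1d_bwd <- function(cache, dout) {
  with(cache, {
    dx <- array(0, c(N, L, C))
    for (p in seq_len(pool)) {
      mask <- arg == p
      if (!any(mask)) next
      cols <- seq(p, by = stride, length.out = Lo)
      sl <- dx[, cols, , drop = FALSE]
      sl[mask] <- sl[mask] + dout[mask]
      dx[, cols, ] <- sl
    }
    dx
  })
}

maxpool2d_fwd <- function(x, pool = c(2L, 2L), stride = pool) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Ho <- (H - pool[1]) %/% stride[1] + 1L
  Wo <- (Wd - pool[2]) %/% stride[2] + 1L
  m <- array(-Inf, c(N, Ho, Wo, C)); arg <- array(0L, c(N, Ho, Wo, C))
  for (a in seq_len(pool[1])) for (b in seq_len(pool[2])) {
    rows <- seq(a, by = stride[1], length.out = Ho)
    cols <- seq(b, by = stride[2], length.out = Wo)
    cand <- x[, rows, cols, , drop = FALSE]
    upd <- cand > m
    m[upd] <- cand[upd]; arg[upd] <- (a - 1L) * pool[2] + b
  }
  list(out = m, cache = list(arg = arg, H = H, Wd = Wd, pool = pool,
                             stride = stride, N = N, C = C, Ho = Ho, Wo = Wo))
}

maxpool2d_bwd <- function(cache, dout) {
  with(cache, {
    dx <- array(0, c(N, H, Wd, C))
    for (a in seq_len(pool[1])) for (b in seq_len(pool[2])) {
      mask <- arg == (a - 1L) * pool[2] + b
      if (!any(mask)) next
      rows <- seq(a, by = stride[1], length.out = Ho)
      cols <- seq(b, by = stride[2], length.out = Wo)
      sl <- dx[, rows, cols, , drop = FALSE]
      sl[mask] <- sl[mask] + dout[mask]
      dx[, rows, cols, ] <- sl
    }
    dx
  })
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

dense_fwd <- function(x, W, b) {
  list(out = x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE),
       cache = list(x = x, W = W))
}
dense_bwd <- function(cache, dout) {
  list(dx = dout %*% t(cache$W), dW = t(cache$x) %*% dout,
       db = colSums(dout))
}

# Global average pooling over the time axis: N x L x C -> N x C.
gap1d_fwd <- function(x) {
  d <- dim(x)
  list(out = colMeans(aperm(x, c(2, 1, 3)), dims = 1), cache = d)
}
gap1d_bwd <- function(cache, dout) {
  N <- cache[1]; L <- cache[2]; C <- cache[3]
  aperm(array(dout / L, c(N, C, L)), c(1, 3, 2))
}

# Global max pooling over both spatial axes: N x H x W x C -> N x C.
gmp2d_fwd <- function(x) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  M <- matrix(aperm(x, c(1, 4, 2, 3)), N * C, H * Wd)
  idx <- max.col(M, ties.method = "first")
  list(out = matrix(M[cbind(seq_len(N * C), idx)], N, C),
       cache = list(idx = idx, d = d))
}
gmp2d_bwd <- function(cache, dout) {
  d <- cache$d; N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  dM <- matrix(0, N * C, H * Wd)
  dM[cbind(seq_len(N * C), cache$idx)] <- as.numeric(dout)
  aperm(array(dM, c(N, C, H, Wd)), c(1, 3, 4, 2))
}

# Mean over the frequency axis: N x H x W x C -> N x W x C (sequence mode).
freqmean_fwd <- function(x) {
  d <- dim(x)
  list(out = colMeans(aperm(x, c(2, 1, 3, 4)), dims = 1), cache = d)
}
freqmean_bwd <- function(cache, dout) {
  N <- cache[1]; H <- cache[2]; Wd <- cache[3]; C <- cache[4]
  aperm(array(dout / H, c(N, Wd, C, H)), c(1, 4, 2, 3))
}

# Inverted dropout; identity at inference.
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, cache = mask)
}
dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# LSTM over N x T x D; returns the last hidden state (N x H).
# Gate order in the fused weight matrices: input, forget, cell, output.
lstm_fwd <- function(x, Wx, Wh, b) {
  d <- dim(x); N <- d[1]; Tn <- d[2]; D <- d[3]
  H <- ncol(Wh) %/% 4L
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  gates <- vector("list", Tn); cs <- vector("list", Tn)
  hs <- vector("list", Tn)
  bmat <- matrix(b, N, 4L * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], N, D)
    z <- xt %*% Wx + h %*% Wh + bmat
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, H + 1:H, drop = FALSE])
    g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(z[, 3 * H + 1:H, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    h <- o * tanh(cc)
    gates[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev)
    cs[[t]] <- cc; hs[[t]] <- h
  }
  list(out = h, cache = list(x = x, Wx = Wx, Wh = Wh, gates = gates,
                             cs = cs, hs = hs, N = N, Tn = Tn, D = D, H = H))
}

lstm_bwd <- function(cache, dh_last) {
  with(cache, {
    dWx <- matrix(0, nrow(Wx), ncol(Wx))
    dWh <- matrix(0, nrow(Wh), ncol(Wh))
    db <- numeric(4L * H)
    dx <- array(0, c(N, Tn, D))
    dh <- dh_last; dc <- matrix(0, N, H)
    for (t in rev(seq_len(Tn))) {
      gt <- gates[[t]]
      tc <- tanh(cs[[t]])
      do_ <- dh * tc
      dct <- dc + dh * gt$o * (1 - tc^2)
      di <- dct * gt$g
      dg <- dct * gt$i
      df <- dct * gt$c_prev
      dc <- dct * gt$f
      dz <- cbind(di * gt$i * (1 - gt$i),
                  df * gt$f * (1 - gt$f),
                  dg * (1 - gt$g^2),
                  do_ * gt$o * (1 - gt$o))
      xt <- matrix(x[, t, ], N, D)
      h_prev <- if (t == 1) matrix(0, N, H) else hs[[t - 1]]
      dWx <- dWx + t(xt) %*% dz
      dWh <- dWh + t(h_prev) %*% dz
      db <- db + colSums(dz)
      dx[, t, ] <- dz %*% t(Wx)
      dh <- dz %*% t(Wh)
    }
    list(dx = dx, dWx = dWx, dWh = dWh, db = db)
  })
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, frozen = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
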