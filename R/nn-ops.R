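# Low-level neural-network primitives on BLAS matrix ops.
#
# Conventions:
#   * feature maps are numeric arrays dim (C, L, B): channels, length, batch
#   * dense activations are matrices (F, B)
#   * every *_fwd returns list(out, cache); every *_bwd takes (dout, cache)
#     and returns list(dx, <param grads named like the params>)
# All ops are deterministic given R's RNG state (dropout is the only
# stochastic op).

# 1-D convolution, stride 1, 'same' zero padding, via C++ im2col + BLAS GEMM.
# W: (Cout, Cin*k) with columns ordered channel-fastest; b: length Cout.
conv1d_fwd <- function(X, W, b, k) {
  d <- dim(X)
  C <- d[1]; L <- d[2]; B <- d[3]
  M <- cpp_im2col(X, C, L, B, k)
  Y <- W %*% M + b
  dim(Y) <- c(nrow(W), L, B)
  list(out = Y, cache = list(M = M, C = C, L = L, B = B, k = k))
}

conv1d_bwd <- function(dY, cache, W) {
  C <- cache$C; L <- cache$L; B <- cache$B; k <- cache$k
  dYm <- dY
  dim(dYm) <- c(nrow(W), L * B)
  dW <- tcrossprod(dYm, cache$M)
  db <- rowSums(dYm)
  dM <- crossprod(W, dYm)                      # (C*k, L*B)
  dx <- cpp_col2im(dM, C, L, B, k)
  dim(dx) <- c(C, L, B)
  list(dx = dx, dW = dW, db = db)
}

elu_fwd <- function(X) {
  neg <- X < 0
  Y <- X
  Y[neg] <- exp(X[neg]) - 1
  list(out = Y, cache = list(neg = neg, Y = Y))
}

elu_bwd <- function(dY, cache) {
  dX <- dY
  dX[cache$neg] <- dY[cache$neg] * (cache$Y[cache$neg] + 1)
  list(dx = dX)
}

relu_fwd <- function(X) {
  mask <- X > 0
  Y <- X * mask
  list(out = Y, cache = mask)
}

relu_bwd <- function(dY, cache) list(dx = dY * cache)

# Max pooling by integer factor p along length; trailing remainder dropped.
maxpool_fwd <- function(X, p) {
  d <- dim(X)
  C <- d[1]; L <- d[2]; B <- d[3]
  Lo <- L %/% p
  Xr <- array(X[, seq_len(Lo * p), , drop = FALSE], c(C, p, Lo, B))
  Y <- array(Xr[, 1, , , drop = FALSE], c(C, Lo, B))
  A <- array(1L, c(C, Lo, B))
  if (p > 1) for (i in 2:p) {
    Xi <- array(Xr[, i, , , drop = FALSE], c(C, Lo, B))
    m <- Xi > Y
    Y[m] <- Xi[m]
    A[m] <- i
  }
  list(out = Y, cache = list(A = A, p = p, L = L, C = C, B = B, Lo = Lo))
}

maxpool_bwd <- function(dY, cache) {
  C <- cache$C; L <- cache$L; B <- cache$B
  p <- cache$p; Lo <- cache$Lo
  dXr <- array(0, c(C, p, Lo, B))
  for (i in seq_len(p)) {
    tmp <- dY
    tmp[cache$A != i] <- 0
    dXr[, i, , ] <- tmp
  }
  dX <- array(0, c(C, L, B))
  dX[, seq_len(p * Lo), ] <- array(dXr, c(C, p * Lo, B))
  list(dx = dX)
}

dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) return(list(out = X, cache = NULL))
  mask <- array((runif(length(X)) >= rate) / (1 - rate), dim(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) return(list(dx = dY))
  list(dx = dY * cache)
}

# Batch normalization over (length x batch) per channel.
# params: gamma, beta (length C); state: running_mean, running_var.
bn_fwd <- function(X, gamma, beta, state, mode, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  C <- d[1]; n <- d[2] * d[3]
  Xm <- matrix(X, C)
  if (mode == "train") {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm * Xm) - mu * mu
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * inv
  Y <- array(gamma * xhat + beta, d)
  list(out = Y, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d, mode = mode))
}

bn_bwd <- function(dY, cache) {
  d <- cache$d
  C <- d[1]; n <- d[2] * d[3]
  dYm <- matrix(dY, C)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  if (cache$mode == "train") {
    dxhat <- dYm * cache$gamma
    dXm <- cache$inv * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dXm <- dYm * cache$gamma * cache$inv
  }
  list(dx = array(dXm, d), dgamma = dgamma, dbeta = dbeta)
}

dense_fwd <- function(X, W, b) {
  list(out = W %*% X + b, cache = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dx = crossprod(W, dY), dW = dY %*% t(cache), db = rowSums(dY))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Nearest-neighbour upsampling by integer factor along length.
upsample_fwd <- function(X, f) {
  L <- dim(X)[2]
  list(out = X[, rep(seq_len(L), each = f), , drop = FALSE],
       cache = list(f = f, L = L))
}

upsample_bwd <- function(dY, cache) {
  d <- dim(dY)
  C <- d[1]; B <- d[3]
  f <- cache$f; L <- cache$L
  dYr <- array(dY, c(C, f, L, B))
  dX <- array(dYr[, 1, , , drop = FALSE], c(C, L, B))
  if (f > 1) for (i in 2:f) {
    dX <- dX + array(dYr[, i, , , drop = FALSE], c(C, L, B))
  }
  list(dx = dX)
}

# Adaptive mean pooling into s near-equal bins (PyTorch-style boundaries).
.bin_bounds <- function(T, s) {
  lo <- floor((seq_len(s) - 1L) * T / s) + 1L
  hi <- floor(seq_len(s) * T / s)
  cbind(lo, hi)
}

adaptive_meanpool_fwd <- function(X, s) {
  d <- dim(X)
  bb <- .bin_bounds(d[2], s)
  Y <- array(0, c(d[1], s, d[3]))
  for (i in seq_len(s)) {
    seg <- X[, bb[i, 1]:bb[i, 2], , drop = FALSE]
    Y[, i, ] <- array(seg, c(d[1], bb[i, 2] - bb[i, 1] + 1L, d[3])) |>
      (\(a) {
        acc <- array(a[, 1, , drop = FALSE], c(d[1], d[3]))
        w <- dim(a)[2]
        if (w > 1) for (j in 2:w) acc <- acc + array(a[, j, , drop = FALSE], c(d[1], d[3]))
        acc / w
      })()
  }
  list(out = Y, cache = list(bb = bb, d = d))
}

adaptive_meanpool_bwd <- function(dY, cache) {
  d <- cache$d
  bb <- cache$bb
  dX <- array(0, c(d[1], d[2], d[3]))
  for (i in seq_len(nrow(bb))) {
    w <- bb[i, 2] - bb[i, 1] + 1L
    g <- array(dY[, i, , drop = FALSE], c(d[1], d[3])) / w
    for (j in bb[i, 1]:bb[i, 2]) dX[, j, ] <- dX[, j, ] + g
  }
  list(dx = dX)
}

# Replicate bin values back over their original extent (SPPM upsample).
bin_upsample_fwd <- function(Y, bb, T) {
  d <- dim(Y)
  X <- array(0, c(d[1], T, d[3]))
  for (i in seq_len(nrow(bb))) {
    w <- bb[i, 2] - bb[i, 1] + 1L
    X[, bb[i, 1]:bb[i, 2], ] <- Y[, rep(i, w), , drop = FALSE]
  }
  list(out = X, cache = list(bb = bb, d = d))
}

bin_upsample_bwd <- function(dX, cache) {
  bb <- cache$bb
  d <- cache$d
  dY <- array(0, d)
  for (i in seq_len(nrow(bb))) {
    seg <- dX[, bb[i, 1]:bb[i, 2], , drop = FALSE]
    w <- bb[i, 2] - bb[i, 1] + 1L
    acc <- array(seg[, 1, , drop = FALSE], c(d[1], d[3]))
    if (w > 1) for (j in 2:w) acc <- acc + array(seg[, j, , drop = FALSE], c(d[1], d[3]))
    dY[, i, ] <- acc
  }
  list(dx = dY)
}

global_meanpool_fwd <- function(X) {
  d <- dim(X)
  Y <- matrix(0, d[1], d[3])
  for (b in seq_len(d[3])) Y[, b] <- rowMeans(matrix(X[, , b], d[1]))
  list(out = Y, cache = d)
}

global_meanpool_bwd <- function(dY, cache) {
  d <- cache
  dX <- array(0, d)
  for (b in seq_len(d[3])) dX[, , b] <- matrix(dY[, b], d[1], d[2]) / d[2]
  list(dx = dX)
}

global_maxpool_fwd <- function(X) {
  d <- dim(X)
  Y <- matrix(0, d[1], d[3])
  A <- matrix(0L, d[1], d[3])
  for (b in seq_len(d[3])) {
    Xb <- matrix(X[, , b], d[1])
    A[, b] <- max.col(Xb, ties.method = "first")
    Y[, b] <- Xb[cbind(seq_len(d[1]), A[, b])]
  }
  list(out = Y, cache = list(A = A, d = d))
}

global_maxpool_bwd <- function(dY, cache) {
  d <- cache$d
  dX <- array(0, d)
  for (b in seq_len(d[3])) {
    dXb <- matrix(0, d[1], d[2])
    dXb[cbind(seq_len(d[1]), cache$A[, b])] <- dY[, b]
    dX[, , b] <- dXb
  }
  list(dx = dX)
}

# ---- Gated recurrent unit (single direction) --------------------------------

# params: Wz, Wr, Wh (H x C); Uz, Ur, Uh (H x H); bz, br, bh (H)
gru_dir_fwd <- function(X, p, reverse = FALSE) {
  d <- dim(X)
  C <- d[1]; T <- d[2]; B <- d[3]
  H <- nrow(p$Wz)
  ts <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, H, B)
  out <- array(0, c(H, T, B))
  steps <- vector("list", T)
  for (s in seq_len(T)) {
    t <- ts[s]
    x <- matrix(X[, t, ], C, B)
    z <- sigmoid(p$Wz %*% x + p$Uz %*% h + p$bz)
    r <- sigmoid(p$Wr %*% x + p$Ur %*% h + p$br)
    rh <- r * h
    hh <- tanh(p$Wh %*% x + p$Uh %*% rh + p$bh)
    hn <- (1 - z) * h + z * hh
    steps[[s]] <- list(x = x, z = z, r = r, hh = hh, hprev = h, rh = rh)
    h <- hn
    out[, t, ] <- h
  }
  list(out = out, cache = list(steps = steps, ts = ts, C = C, T = T, B = B, H = H))
}

gru_dir_bwd <- function(dOut, cache, p) {
  C <- cache$C; T <- cache$T; B <- cache$B; H <- cache$H
  g <- lapply(p, function(a) a * 0)   # zero grads with the params' exact shapes
  dX <- array(0, c(C, T, B))
  dh <- matrix(0, H, B)
  for (s in rev(seq_len(T))) {
    t <- cache$ts[s]
    st <- cache$steps[[s]]
    dht <- dh + matrix(dOut[, t, ], H, B)
    dz <- dht * (st$hh - st$hprev)
    dhh <- dht * st$z
    dhprev <- dht * (1 - st$z)
    dah <- dhh * (1 - st$hh^2)
    g$Wh <- g$Wh + dah %*% t(st$x)
    g$Uh <- g$Uh + dah %*% t(st$rh)
    g$bh <- g$bh + rowSums(dah)
    drh <- crossprod(p$Uh, dah)
    dr <- drh * st$hprev
    dhprev <- dhprev + drh * st$r
    daz <- dz * st$z * (1 - st$z)
    dar <- dr * st$r * (1 - st$r)
    g$Wz <- g$Wz + daz %*% t(st$x)
    g$Uz <- g$Uz + daz %*% t(st$hprev)
    g$bz <- g$bz + rowSums(daz)
    g$Wr <- g$Wr + dar %*% t(st$x)
    g$Ur <- g$Ur + dar %*% t(st$hprev)
    g$br <- g$br + rowSums(dar)
    dhprev <- dhprev + crossprod(p$Uz, daz) + crossprod(p$Ur, dar)
    dX[, t, ] <- crossprod(p$Wz, daz) + crossprod(p$Wr, dar) + crossprod(p$Wh, dah)
    dh <- dhprev
  }
  list(dx = dX, grads = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Parameter initialisation ----------------------------------------------

init_conv_w <- function(cout, cin, k) {
  matrix(rnorm(cout * cin * k, sd = sqrt(2 / (cin * k))), cout, cin * k)
}

init_dense_w <- function(cout, cin) {
  matrix(rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin)
}

init_gru_params <- function(H, C) {
  u <- function(n, m) matrix(runif(n * m, -1, 1) * sqrt(1 / m), n, m)
  list(Wz = u(H, C), Wr = u(H, C), Wh = u(H, C),
       Uz = u(H, H), Ur = u(H, H), Uh = u(H, H),
       bz = numeric(H), br = numeric(H), bh = numeric(H))
}

# ---- ADAM -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Elementwise value clipping (clip_value), optional decoupled-style L2 weight
# decay folded into the gradient, standard ADAM moments.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0, clip_value = NULL,
                      skip_decay = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !(nm %in% skip_decay)) {
      g <- g + weight_decay * params[[nm]]
    }
    if (!is.null(clip_value)) g <- pmin(pmax(g, -clip_value), clip_value)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
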