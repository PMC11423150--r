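# NLDNN architecture: U-shaped encoder (generator) / decoder (predictor),
# species discriminator, and a sequence-level regression baseline.
#
# A model is list(params, bn_state, config) of class "nldnn_model".
# Parameters live in one flat named list so ADAM, checkpointing and the
# generator/predictor partition are all name-based and exact.

#' Model configuration
#'
#' Architecture hyperparameters of the nucleotide-level network. The reference
#' topology is fixed (three conv blocks + bidirectional GRU + pyramid pooling
#' in the encoder; three refinement residual skip fusions; three up-sample
#' blocks + a width-1 linear output head) but layer sizes are configurable.
#'
#' @param in_channels 4 for DNA one-hot, 5 with a chromatin-accessibility row.
#' @param conv_channels integer(3), encoder conv widths.
#' @param conv_kernels integer(3), encoder kernel sizes.
#' @param pool_sizes integer(3), max-pool factors; their product must divide
#'   the training window length.
#' @param dropout dropout rate in encoder/discriminator blocks.
#' @param gru_hidden hidden units per GRU direction.
#' @param sppm_scales integer vector of pyramid pooling bin counts.
#' @param disc_channels integer(3), discriminator conv widths.
#' @param disc_hidden discriminator fully-connected width.
#' @param seed integer; parameter initialisation seed.
#' @return list of class "nldnn_config".
#' @export
model_config <- function(in_channels = 4L,
                         conv_channels = c(64L, 128L, 256L),
                         conv_kernels = c(15L, 5L, 3L),
                         pool_sizes = c(5L, 2L, 2L),
                         dropout = 0.2,
                         gru_hidden = 128L,
                         sppm_scales = c(1L, 2L, 4L),
                         disc_channels = c(32L, 32L, 32L),
                         disc_hidden = 64L,
                         seed = 1L) {
  stopifnot(length(conv_channels) == 3, length(conv_kernels) == 3,
            length(pool_sizes) == 3, dropout >= 0, dropout < 1,
            all(pool_sizes >= 1), in_channels %in% c(4L, 5L))
  structure(list(in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 conv_kernels = as.integer(conv_kernels),
                 pool_sizes = as.integer(pool_sizes),
                 dropout = dropout,
                 gru_hidden = as.integer(gru_hidden),
                 sppm_scales = as.integer(sppm_scales),
                 disc_channels = as.integer(disc_channels),
                 disc_hidden = as.integer(disc_hidden),
                 seed = as.integer(seed)),
            class = "nldnn_config")
}

# Compact configuration used throughout the package's own experiments:
# same topology, smaller widths, sized for minutes-scale CPU training.
#' @rdname model_config
#' @export
desk_config <- function(seed = 1L, in_channels = 4L) {
  model_config(in_channels = in_channels,
               conv_channels = c(12L, 16L, 20L),
               conv_kernels = c(15L, 5L, 3L),
               pool_sizes = c(5L, 2L, 2L),
               dropout = 0.2,
               gru_hidden = 8L,
               sppm_scales = c(1L, 2L, 4L),
               disc_channels = c(16L, 16L, 16L),
               disc_hidden = 32L,
               seed = seed)
}

.flatten_gru <- function(p, prefix) {
  names(p) <- paste0(prefix, "_", names(p))
  p
}

#' Build the nucleotide-level network
#'
#' Deterministic given `config$seed`: two builds from the same config are
#' parameter-identical.
#'
#' @param config a [model_config()].
#' @return object of class "nldnn_model".
#' @export
build_nldnn <- function(config) {
  set.seed(config$seed)
  cc <- config$conv_channels
  ck <- config$conv_kernels
  g <- config$gru_hidden
  params <- list()
  params$enc1_W <- init_conv_w(cc[1], config$in_channels, ck[1])
  params$enc1_b <- numeric(cc[1])
  params$enc2_W <- init_conv_w(cc[2], cc[1], ck[2])
  params$enc2_b <- numeric(cc[2])
  params$enc3_W <- init_conv_w(cc[3], cc[2], ck[3])
  params$enc3_b <- numeric(cc[3])
  params <- c(params,
              .flatten_gru(init_gru_params(g, cc[3]), "gruf"),
              .flatten_gru(init_gru_params(g, cc[3]), "grur"))
  params$gproj_W <- init_conv_w(cc[3], 2L * g, 1L)
  params$gproj_b <- numeric(cc[3])
  for (i in seq_along(config$sppm_scales)) {
    params[[paste0("sppm", i, "_W")]] <- init_conv_w(cc[3], cc[3], 1L)
    params[[paste0("sppm", i, "_b")]] <- numeric(cc[3])
  }
  bn_state <- list()
  # refinement residual blocks at widths c3, c2, c1 (levels 3, 2, 1)
  for (lev in 3:1) {
    w <- cc[lev]
    pre <- paste0("rrb", lev)
    params[[paste0(pre, "_s_W")]] <- init_conv_w(w, w, 1L)
    params[[paste0(pre, "_s_b")]] <- numeric(w)
    params[[paste0(pre, "_a_W")]] <- init_conv_w(w, w, 3L)
    params[[paste0(pre, "_a_b")]] <- numeric(w)
    params[[paste0(pre, "_c_W")]] <- init_conv_w(w, w, 3L)
    params[[paste0(pre, "_c_b")]] <- numeric(w)
    params[[paste0(pre, "_bn_gamma")]] <- rep(1, w)
    params[[paste0(pre, "_bn_beta")]] <- numeric(w)
    bn_state[[paste0(pre, "_bn")]] <- list(running_mean = numeric(w),
                                           running_var = rep(1, w))
  }
  # up-sample blocks: upsample -> BN -> ReLU -> conv, widths c3->c2->c1->c1
  upin <- c(cc[3], cc[2], cc[1])
  upout <- c(cc[2], cc[1], cc[1])
  for (i in 1:3) {
    pre <- paste0("up", i)
    params[[paste0(pre, "_bn_gamma")]] <- rep(1, upin[i])
    params[[paste0(pre, "_bn_beta")]] <- numeric(upin[i])
    bn_state[[paste0(pre, "_bn")]] <- list(running_mean = numeric(upin[i]),
                                           running_var = rep(1, upin[i]))
    params[[paste0(pre, "_W")]] <- init_conv_w(upout[i], upin[i], 3L)
    params[[paste0(pre, "_b")]] <- numeric(upout[i])
  }
  params$out_W <- init_conv_w(1L, cc[1], 1L)
  params$out_b <- numeric(1L)
  structure(list(params = params, bn_state = bn_state, config = config),
            class = "nldnn_model")
}

# name-based generator/predictor partition
.gen_regex <- "^(enc|gruf|grur|gproj|sppm)"

generator_param_names <- function(params) {
  grep(.gen_regex, names(params), value = TRUE)
}

predictor_param_names <- function(params) {
  setdiff(names(params), generator_param_names(params))
}

# parameters entering the L2 penalty / weight decay (weight matrices only)
weight_param_names <- function(params) {
  grep("(_W$)|(^gru[fr]_[WU])", names(params), value = TRUE)
}

#' Split a model into its generator and predictor
#'
#' The generator is the encoder (conv blocks, bidirectional GRU, pyramid
#' pooling) emitting three same-level skip features plus the bottleneck; the
#' predictor is the refinement residual blocks, the up-sampling decoder and
#' the output head. Composing the two reproduces the full forward pass
#' exactly.
#'
#' @param model an "nldnn_model".
#' @return list(generator, predictor), each with params (+ bn_state, config).
#' @export
split_generator_predictor <- function(model) {
  gn <- generator_param_names(model$params)
  pn <- predictor_param_names(model$params)
  list(generator = list(params = model$params[gn], config = model$config),
       predictor = list(params = model$params[pn], bn_state = model$bn_state,
                        config = model$config))
}

# ---- generator forward/backward --------------------------------------------

# X: (in_channels, L, B); returns skips s1 (c1, L/p1), s2, s3 and bottleneck
# (c3, L/(p1 p2 p3)). Input length must be divisible by prod(pool_sizes);
# nldnn_predict() handles padding for arbitrary lengths.
generator_forward <- function(params, config, X, mode = "eval") {
  ck <- config$conv_kernels
  pp <- config$pool_sizes
  dr <- config$dropout
  cache <- list()
  c1 <- conv1d_fwd(X, params$enc1_W, params$enc1_b, ck[1]); cache$c1 <- c1$cache
  e1 <- elu_fwd(c1$out); cache$e1 <- e1$cache
  m1 <- maxpool_fwd(e1$out, pp[1]); cache$m1 <- m1$cache
  d1 <- dropout_fwd(m1$out, dr, mode); cache$d1 <- d1$cache
  s1 <- d1$out

  c2 <- conv1d_fwd(s1, params$enc2_W, params$enc2_b, ck[2]); cache$c2 <- c2$cache
  e2 <- elu_fwd(c2$out); cache$e2 <- e2$cache
  m2 <- maxpool_fwd(e2$out, pp[2]); cache$m2 <- m2$cache
  d2 <- dropout_fwd(m2$out, dr, mode); cache$d2 <- d2$cache
  s2 <- d2$out

  c3 <- conv1d_fwd(s2, params$enc3_W, params$enc3_b, ck[3]); cache$c3 <- c3$cache
  e3 <- elu_fwd(c3$out); cache$e3 <- e3$cache
  m3 <- maxpool_fwd(e3$out, pp[3]); cache$m3 <- m3$cache
  d3 <- dropout_fwd(m3$out, dr, mode); cache$d3 <- d3$cache
  s3 <- d3$out

  gf <- gru_dir_fwd(s3, .unflatten_gru(params, "gruf")); cache$gf <- gf$cache
  gr <- gru_dir_fwd(s3, .unflatten_gru(params, "grur"), reverse = TRUE)
  cache$gr <- gr$cache
  gcat <- abind2(gf$out, gr$out)
  pj <- conv1d_fwd(gcat, params$gproj_W, params$gproj_b, 1L); cache$pj <- pj$cache
  z <- pj$out

  T <- dim(z)[2]
  fused <- z
  cache$sppm <- vector("list", length(config$sppm_scales))
  for (i in seq_along(config$sppm_scales)) {
    s <- config$sppm_scales[i]
    ap <- adaptive_meanpool_fwd(z, s)
    pc <- conv1d_fwd(ap$out, params[[paste0("sppm", i, "_W")]],
                     params[[paste0("sppm", i, "_b")]], 1L)
    bu <- bin_upsample_fwd(pc$out, ap$cache$bb, T)
    fused <- fused + bu$out
    cache$sppm[[i]] <- list(ap = ap$cache, pc = pc$cache, bu = bu$cache)
  }
  list(skips = list(s1 = s1, s2 = s2, s3 = s3), bottleneck = fused,
       cache = cache)
}

.unflatten_gru <- function(params, prefix) {
  nm <- c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh", "bz", "br", "bh")
  p <- params[paste0(prefix, "_", nm)]
  names(p) <- nm
  p
}

# stack two (C,T,B) arrays along channels
abind2 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# dfeats: list(ds1, ds2, ds3, dbottleneck); returns grads + dX
generator_backward <- function(dfeats, cache, params, config) {
  g <- list()
  dz <- dfeats$dbottleneck
  for (i in rev(seq_along(config$sppm_scales))) {
    sc <- cache$sppm[[i]]
    dbu <- bin_upsample_bwd(dfeats$dbottleneck, sc$bu)
    dpc <- conv1d_bwd(dbu$dx, sc$pc, params[[paste0("sppm", i, "_W")]])
    g[[paste0("sppm", i, "_W")]] <- dpc$dW
    g[[paste0("sppm", i, "_b")]] <- dpc$db
    dap <- adaptive_meanpool_bwd(dpc$dx, sc$ap)
    dz <- dz + dap$dx
  }
  dpj <- conv1d_bwd(dz, cache$pj, params$gproj_W)
  g$gproj_W <- dpj$dW
  g$gproj_b <- dpj$db
  H <- config$gru_hidden
  dgf <- dpj$dx[seq_len(H), , , drop = FALSE]
  dgr <- dpj$dx[H + seq_len(H), , , drop = FALSE]
  bf <- gru_dir_bwd(dgf, cache$gf, .unflatten_gru(params, "gruf"))
  br <- gru_dir_bwd(dgr, cache$gr, .unflatten_gru(params, "grur"))
  for (nm in names(bf$grads)) g[[paste0("gruf_", nm)]] <- bf$grads[[nm]]
  for (nm in names(br$grads)) g[[paste0("grur_", nm)]] <- br$grads[[nm]]
  ds3 <- bf$dx + br$dx + dfeats$ds3

  dd3 <- dropout_bwd(ds3, cache$d3)
  dm3 <- maxpool_bwd(dd3$dx, cache$m3)
  de3 <- elu_bwd(dm3$dx, cache$e3)
  dc3 <- conv1d_bwd(de3$dx, cache$c3, params$enc3_W)
  g$enc3_W <- dc3$dW; g$enc3_b <- dc3$db
  ds2 <- dc3$dx + dfeats$ds2

  dd2 <- dropout_bwd(ds2, cache$d2)
  dm2 <- maxpool_bwd(dd2$dx, cache$m2)
  de2 <- elu_bwd(dm2$dx, cache$e2)
  dc2 <- conv1d_bwd(de2$dx, cache$c2, params$enc2_W)
  g$enc2_W <- dc2$dW; g$enc2_b <- dc2$db
  ds1 <- dc2$dx + dfeats$ds1

  dd1 <- dropout_bwd(ds1, cache$d1)
  dm1 <- maxpool_bwd(dd1$dx, cache$m1)
  de1 <- elu_bwd(dm1$dx, cache$e1)
  dc1 <- conv1d_bwd(de1$dx, cache$c1, params$enc1_W)
  g$enc1_W <- dc1$dW; g$enc1_b <- dc1$db
  list(grads = g, dx = dc1$dx)
}

# ---- predictor forward/backward --------------------------------------------

.rrb_fwd <- function(dec, skip, params, bn_state, pre, mode) {
  cs <- conv1d_fwd(skip, params[[paste0(pre, "_s_W")]],
                   params[[paste0(pre, "_s_b")]], 1L)
  f <- cs$out + dec
  ca <- conv1d_fwd(f, params[[paste0(pre, "_a_W")]],
                   params[[paste0(pre, "_a_b")]], 3L)
  bn <- bn_fwd(ca$out, params[[paste0(pre, "_bn_gamma")]],
               params[[paste0(pre, "_bn_beta")]],
               bn_state[[paste0(pre, "_bn")]], mode)
  rl <- relu_fwd(bn$out)
  cc <- conv1d_fwd(rl$out, params[[paste0(pre, "_c_W")]],
                   params[[paste0(pre, "_c_b")]], 3L)
  bn_state[[paste0(pre, "_bn")]] <- bn$state
  list(out = f + cc$out, bn_state = bn_state,
       cache = list(cs = cs$cache, ca = ca$cache, bn = bn$cache,
                    rl = rl$cache, cc = cc$cache))
}

.rrb_bwd <- function(dout, cache, params, pre) {
  g <- list()
  dcc <- conv1d_bwd(dout, cache$cc, params[[paste0(pre, "_c_W")]])
  g[[paste0(pre, "_c_W")]] <- dcc$dW
  g[[paste0(pre, "_c_b")]] <- dcc$db
  drl <- relu_bwd(dcc$dx, cache$rl)
  dbn <- bn_bwd(drl$dx, cache$bn)
  g[[paste0(pre, "_bn_gamma")]] <- dbn$dgamma
  g[[paste0(pre, "_bn_beta")]] <- dbn$dbeta
  dca <- conv1d_bwd(dbn$dx, cache$ca, params[[paste0(pre, "_a_W")]])
  g[[paste0(pre, "_a_W")]] <- dca$dW
  g[[paste0(pre, "_a_b")]] <- dca$db
  df <- dout + dca$dx
  dcs <- conv1d_bwd(df, cache$cs, params[[paste0(pre, "_s_W")]])
  g[[paste0(pre, "_s_W")]] <- dcs$dW
  g[[paste0(pre, "_s_b")]] <- dcs$db
  list(grads = g, ddec = df, dskip = dcs$dx)
}

.upblock_fwd <- function(X, params, bn_state, pre, factor, mode) {
  us <- upsample_fwd(X, factor)
  bn <- bn_fwd(us$out, params[[paste0(pre, "_bn_gamma")]],
               params[[paste0(pre, "_bn_beta")]],
               bn_state[[paste0(pre, "_bn")]], mode)
  rl <- relu_fwd(bn$out)
  cv <- conv1d_fwd(rl$out, params[[paste0(pre, "_W")]],
                   params[[paste0(pre, "_b")]], 3L)
  bn_state[[paste0(pre, "_bn")]] <- bn$state
  list(out = cv$out, bn_state = bn_state,
       cache = list(us = us$cache, bn = bn$cache, rl = rl$cache, cv = cv$cache))
}

.upblock_bwd <- function(dout, cache, params, pre) {
  g <- list()
  dcv <- conv1d_bwd(dout, cache$cv, params[[paste0(pre, "_W")]])
  g[[paste0(pre, "_W")]] <- dcv$dW
  g[[paste0(pre, "_b")]] <- dcv$db
  drl <- relu_bwd(dcv$dx, cache$rl)
  dbn <- bn_bwd(drl$dx, cache$bn)
  g[[paste0(pre, "_bn_gamma")]] <- dbn$dgamma
  g[[paste0(pre, "_bn_beta")]] <- dbn$dbeta
  dus <- upsample_bwd(dbn$dx, cache$us)
  list(grads = g, dx = dus$dx)
}

# feats: output of generator_forward (skips + bottleneck)
predictor_forward <- function(params, bn_state, config, feats, mode = "eval") {
  pp <- config$pool_sizes
  cache <- list()
  r3 <- .rrb_fwd(feats$bottleneck, feats$skips$s3, params, bn_state, "rrb3", mode)
  bn_state <- r3$bn_state; cache$r3 <- r3$cache
  u1 <- .upblock_fwd(r3$out, params, bn_state, "up1", pp[3], mode)
  bn_state <- u1$bn_state; cache$u1 <- u1$cache
  r2 <- .rrb_fwd(u1$out, feats$skips$s2, params, bn_state, "rrb2", mode)
  bn_state <- r2$bn_state; cache$r2 <- r2$cache
  u2 <- .upblock_fwd(r2$out, params, bn_state, "up2", pp[2], mode)
  bn_state <- u2$bn_state; cache$u2 <- u2$cache
  r1 <- .rrb_fwd(u2$out, feats$skips$s1, params, bn_state, "rrb1", mode)
  bn_state <- r1$bn_state; cache$r1 <- r1$cache
  u3 <- .upblock_fwd(r1$out, params, bn_state, "up3", pp[1], mode)
  bn_state <- u3$bn_state; cache$u3 <- u3$cache
  ov <- conv1d_fwd(u3$out, params$out_W, params$out_b, 1L)
  cache$ov <- ov$cache
  d <- dim(ov$out)
  list(pred = matrix(ov$out, d[2], d[3]), cache = cache, bn_state = bn_state)
}

predictor_backward <- function(dpred, cache, params) {
  d <- dim(dpred)
  dov <- array(dpred, c(1L, d[1], d[2]))
  g <- list()
  bo <- conv1d_bwd(dov, cache$ov, params$out_W)
  g$out_W <- bo$dW; g$out_b <- bo$db
  b3 <- .upblock_bwd(bo$dx, cache$u3, params, "up3"); g <- c(g, b3$grads)
  q1 <- .rrb_bwd(b3$dx, cache$r1, params, "rrb1"); g <- c(g, q1$grads)
  b2 <- .upblock_bwd(q1$ddec, cache$u2, params, "up2"); g <- c(g, b2$grads)
  q2 <- .rrb_bwd(b2$dx, cache$r2, params, "rrb2"); g <- c(g, q2$grads)
  b1 <- .upblock_bwd(q2$ddec, cache$u1, params, "up1"); g <- c(g, b1$grads)
  q3 <- .rrb_bwd(b1$dx, cache$r3, params, "rrb3"); g <- c(g, q3$grads)
  list(grads = g,
       dfeats = list(ds1 = q1$dskip, ds2 = q2$dskip, ds3 = q3$dskip,
                     dbottleneck = q3$ddec))
}

# ---- full model -------------------------------------------------------------

#' Forward pass of the full model
#'
#' Composes the generator and predictor. Input length must be divisible by
#' the pool-size product; use [nldnn_predict()] for arbitrary lengths.
#'
#' @param model an "nldnn_model".
#' @param X array (in_channels, L, B).
#' @param mode "train" (dropout + batch BN stats) or "eval".
#' @return list(pred = L x B matrix, caches, bn_state).
#' @export
nldnn_forward <- function(model, X, mode = "eval") {
  L <- dim(X)[2]
  if (L %% prod(model$config$pool_sizes) != 0) {
    stop("input length ", L, " not divisible by pool product ",
         prod(model$config$pool_sizes), "; use nldnn_predict()")
  }
  gf <- generator_forward(model$params, model$config, X, mode)
  pf <- predictor_forward(model$params, model$bn_state, model$config, gf, mode)
  if (any(!is.finite(pf$pred))) stop("non-finite values in model output")
  list(pred = pf$pred,
       caches = list(gen = gf$cache, prd = pf$cache, feats = gf),
       bn_state = pf$bn_state)
}

# dpred: (L, B) gradient of the loss w.r.t. predictions.
# Returns full grads named like params, plus the input gradient.
nldnn_backward <- function(model, fw, dpred, want_dx = FALSE) {
  pb <- predictor_backward(dpred, fw$caches$prd, model$params)
  gb <- generator_backward(pb$dfeats, fw$caches$gen, model$params, model$config)
  list(grads = c(pb$grads, gb$grads), dx = if (want_dx) gb$dx else NULL)
}

#' Predict per-base coverage for windows of arbitrary length
#'
#' Inputs whose length is not divisible by the pool product are right-padded
#' with zero columns and the prediction is trimmed back, preserving the
#' arbitrary-length contract of the fully convolutional design. By default
#' the prediction is strand-averaged: the window and its reverse complement
#' are both predicted and the (re-aligned) mean is returned — TF binding is
#' strand-symmetric and averaging the two orientations reduces prediction
#' variance.
#'
#' @param model an "nldnn_model".
#' @param X array (in_channels, L, B) or matrix (in_channels, L).
#' @param rc_average average the forward and reverse-complement
#'   predictions (default TRUE).
#' @return L x B matrix of predicted (log-scale) coverage.
#' @export
nldnn_predict <- function(model, X, rc_average = TRUE) {
  if (length(dim(X)) == 2) X <- array(X, c(dim(X), 1L))
  L <- dim(X)[2]
  m <- prod(model$config$pool_sizes)
  Lp <- as.integer(ceiling(L / m) * m)
  if (Lp != L) {
    Xp <- array(0, c(dim(X)[1], Lp, dim(X)[3]))
    Xp[, seq_len(L), ] <- X
    X <- Xp
  }
  pred <- nldnn_forward(model, X, mode = "eval")$pred
  if (rc_average) {
    Xr <- X
    Xr[1:4, , ] <- X[4:1, Lp:1, , drop = FALSE]
    if (dim(X)[1] == 5L) Xr[5L, , ] <- X[5L, Lp:1, , drop = FALSE]
    pr <- nldnn_forward(model, Xr, mode = "eval")$pred
    pred <- (pred + pr[Lp:1, , drop = FALSE]) / 2
  }
  pred[seq_len(L), , drop = FALSE]
}

# ---- discriminator ----------------------------------------------------------

#' Build the species discriminator
#'
#' Three conv blocks (conv, ReLU, max-pool 2, dropout), a batch-norm layer,
#' then two fully-connected layers with ReLU and a sigmoid output giving the
#' probability that a generator bottleneck feature map came from the source
#' species.
#'
#' @param config a [model_config()]; by default the input width is
#'   `conv_channels[3]` and `bottleneck_len` positions.
#' @param bottleneck_len length of the bottleneck feature map.
#' @param in_channels input channel count (override when the discriminator
#'   consumes skip features as well as the bottleneck).
#' @param seed initialisation seed.
#' @return list of class "nldnn_discriminator".
#' @export
build_discriminator <- function(config, bottleneck_len,
                                in_channels = config$conv_channels[3],
                                seed = config$seed) {
  set.seed(seed)
  dc <- config$disc_channels
  cin <- in_channels
  params <- list(
    c1_W = init_conv_w(dc[1], cin, 3L), c1_b = numeric(dc[1]),
    c2_W = init_conv_w(dc[2], dc[1], 3L), c2_b = numeric(dc[2]),
    c3_W = init_conv_w(dc[3], dc[2], 3L), c3_b = numeric(dc[3]),
    bn_gamma = rep(1, dc[3]), bn_beta = numeric(dc[3])
  )
  Tf <- bottleneck_len
  for (i in 1:3) if (Tf >= 2L) Tf <- Tf %/% 2L   # pooling skipped at length 1
  params$fc1_W <- init_dense_w(config$disc_hidden, dc[3] * Tf)
  params$fc1_b <- numeric(config$disc_hidden)
  params$fc2_W <- init_dense_w(1L, config$disc_hidden)
  params$fc2_b <- numeric(1L)
  structure(list(params = params,
                 bn_state = list(bn = list(running_mean = numeric(dc[3]),
                                           running_var = rep(1, dc[3]))),
                 config = config, bottleneck_len = bottleneck_len,
                 flat_len = dc[3] * Tf),
            class = "nldnn_discriminator")
}

disc_forward <- function(disc, X, mode = "eval") {
  p <- disc$params
  dr <- disc$config$dropout
  cache <- list()
  h <- X
  for (i in 1:3) {
    cv <- conv1d_fwd(h, p[[paste0("c", i, "_W")]], p[[paste0("c", i, "_b")]], 3L)
    rl <- relu_fwd(cv$out)
    if (dim(rl$out)[2] >= 2L) {
      mp <- maxpool_fwd(rl$out, 2L)
      mp_cache <- mp$cache
      pooled <- mp$out
    } else {
      mp_cache <- NULL
      pooled <- rl$out
    }
    dp <- dropout_fwd(pooled, dr, mode)
    cache[[paste0("b", i)]] <- list(cv = cv$cache, rl = rl$cache,
                                    mp = mp_cache, dp = dp$cache)
    h <- dp$out
  }
  bn <- bn_fwd(h, p$bn_gamma, p$bn_beta, disc$bn_state$bn, mode)
  cache$bn <- bn$cache
  d <- dim(bn$out)
  flat <- matrix(bn$out, d[1] * d[2], d[3])
  f1 <- dense_fwd(flat, p$fc1_W, p$fc1_b); cache$f1 <- f1$cache
  r1 <- relu_fwd(f1$out); cache$r1 <- r1$cache
  f2 <- dense_fwd(r1$out, p$fc2_W, p$fc2_b); cache$f2 <- f2$cache
  prob <- sigmoid(f2$out)
  cache$prob <- prob
  cache$conv_dim <- d
  list(prob = as.numeric(prob), cache = cache,
       bn_state = list(bn = bn$state))
}

# dprob: gradient w.r.t. the sigmoid output (length B)
disc_backward <- function(disc, cache, dprob) {
  p <- disc$params
  g <- list()
  dlogit <- matrix(dprob * cache$prob * (1 - cache$prob), 1)
  b2 <- dense_bwd(dlogit, cache$f2, p$fc2_W)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  dr1 <- relu_bwd(b2$dx, cache$r1)
  b1 <- dense_bwd(dr1$dx, cache$f1, p$fc1_W)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  d <- cache$conv_dim
  dbn_in <- array(b1$dx, d)
  dbn <- bn_bwd(dbn_in, cache$bn)
  g$bn_gamma <- dbn$dgamma; g$bn_beta <- dbn$dbeta
  dh <- dbn$dx
  for (i in 3:1) {
    bl <- cache[[paste0("b", i)]]
    ddp <- dropout_bwd(dh, bl$dp)
    dmp <- if (is.null(bl$mp)) ddp else maxpool_bwd(ddp$dx, bl$mp)
    drl <- relu_bwd(dmp$dx, bl$rl)
    dcv <- conv1d_bwd(drl$dx, bl$cv, p[[paste0("c", i, "_W")]])
    g[[paste0("c", i, "_W")]] <- dcv$dW
    g[[paste0("c", i, "_b")]] <- dcv$db
    dh <- dcv$dx
  }
  list(grads = g, dx = dh)
}

# ---- sequence-level baseline -------------------------------------------------

#' Build the sequence-level regression baseline
#'
#' A small convolutional network with global max pooling and a linear scalar
#' head, trained to regress the window maximum of coverage. Serves as the
#' sequence-level partner for the max-coverage evaluation bridge.
#'
#' @param config a [model_config()].
#' @param channels conv widths of the two layers.
#' @param kernels kernel sizes.
#' @param seed initialisation seed.
#' @return list of class "nldnn_baseline".
#' @export
build_baseline <- function(config, channels = c(32L, 64L),
                           kernels = c(15L, 5L), seed = config$seed) {
  set.seed(seed)
  params <- list(
    c1_W = init_conv_w(channels[1], config$in_channels, kernels[1]),
    c1_b = numeric(channels[1]),
    c2_W = init_conv_w(channels[2], channels[1], kernels[2]),
    c2_b = numeric(channels[2]),
    fc_W = init_dense_w(1L, channels[2]),
    fc_b = numeric(1L)
  )
  structure(list(params = params, config = config,
                 channels = channels, kernels = kernels),
            class = "nldnn_baseline")
}

baseline_forward <- function(bl, X, mode = "eval") {
  p <- bl$params
  cache <- list()
  c1 <- conv1d_fwd(X, p$c1_W, p$c1_b, bl$kernels[1]); cache$c1 <- c1$cache
  r1 <- relu_fwd(c1$out); cache$r1 <- r1$cache
  m1 <- maxpool_fwd(r1$out, 4L); cache$m1 <- m1$cache
  c2 <- conv1d_fwd(m1$out, p$c2_W, p$c2_b, bl$kernels[2]); cache$c2 <- c2$cache
  r2 <- relu_fwd(c2$out); cache$r2 <- r2$cache
  gm <- global_maxpool_fwd(r2$out); cache$gm <- gm$cache
  fc <- dense_fwd(gm$out, p$fc_W, p$fc_b); cache$fc <- fc$cache
  list(score = as.numeric(fc$out), cache = cache)
}

baseline_backward <- function(bl, cache, dscore) {
  p <- bl$params
  g <- list()
  b <- dense_bwd(matrix(dscore, 1), cache$fc, p$fc_W)
  g$fc_W <- b$dW; g$fc_b <- b$db
  gm <- global_maxpool_bwd(b$dx, cache$gm)
  r2 <- relu_bwd(gm$dx, cache$r2)
  c2 <- conv1d_bwd(r2$dx, cache$c2, p$c2_W)
  g$c2_W <- c2$dW; g$c2_b <- c2$db
  m1 <- maxpool_bwd(c2$dx, cache$m1)
  r1 <- relu_bwd(m1$dx, cache$r1)
  c1 <- conv1d_bwd(r1$dx, cache$c1, p$c1_W)
  g$c1_W <- c1$dW; g$c1_b <- c1$db
  list(grads = g, dx = c1$dx)
}

# ---- checkpointing -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file archive holding the config, parameters and any training state.
#'
#' @param model model object (nldnn_model, discriminator or baseline).
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Describe a model's layers
#'
#' Prints a parameter table (name, shape, count) and the generator/predictor
#' partition for the main model.
#'
#' @param model a model object.
#' @return invisibly, a data.frame of parameter shapes.
#' @export
describe_model <- function(model) {
  tab <- data.frame(
    name = names(model$params),
    shape = vapply(model$params, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, character(1)),
    count = vapply(model$params, length, numeric(1)),
    row.names = NULL
  )
  if (inherits(model, "nldnn_model")) {
    tab$part <- ifelse(tab$name %in% generator_param_names(model$params),
                       "generator", "predictor")
  }
  print(tab, row.names = FALSE)
  cat("total parameters:", sum(tab$count), "\n")
  invisible(tab)
}

# parameter hash for frozen-component contracts
param_hash <- function(params) {
  v <- unlist(params, use.names = FALSE)
  # position-weighted checksum: detects both value and order changes
  sum(v * seq_along(v) %% 97) + sum(v^2)
}
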