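# Dual-path adversarial adaptation of the encoder across species, plus the
# transfer-learning baseline.
#
# The source generator G_s (frozen) and target generator G_t (initialised
# from G_s) feed bottleneck feature maps to a species discriminator D.
# Per round, D minimises the standard binary cross-entropy on
# source-vs-target features (d_steps updates), then G_t minimises the
# inverted-label GAN loss (g_steps updates). The source predictor is frozen
# throughout; at test time target-species windows run through G_t and the
# source predictor.

#' Adaptation configuration
#'
#' Reference protocol defaults: ADAM betas (0.5, 0.9), weight decay 1e-5,
#' generator/discriminator learning rates 1e-5 / 1e-4, 1400 discriminator
#' updates per generator update, gradient clipping at 0.02 or 0.05.
#' [desk_adapt_config()] keeps the ratio's spirit at CPU scale.
#'
#' @param betas ADAM moment parameters.
#' @param weight_decay L2 weight decay folded into gradients.
#' @param lr_generator,lr_discriminator learning rates.
#' @param d_steps,g_steps discriminator/generator updates per round.
#' @param clip_value elementwise gradient clipping bound.
#' @param binding_proportion proportion p of target binding windows mixed
#'   into the target pool (0, 0.001, 0.1, 0.5 or 1 in the protocol).
#' @param batch_size windows per adversarial batch.
#' @param max_rounds hard cap on adversarial rounds.
#' @param early_stop stop when the round metric fails to improve on the
#'   previous round (the protocol's rule); FALSE runs all `max_rounds`.
#' @param disc_input "bottleneck" feeds only the bottleneck feature map to
#'   the discriminator (the minimal reading of the dual-path diagram);
#'   "all" additionally feeds the three skip features, mean-pooled to the
#'   bottleneck length and stacked along channels, so the adversarial
#'   gradient also reaches the high-resolution features the predictor's
#'   skip fusions consume.
#' @param lr_head learning rate of the transfer-learning classifier head.
#' @param tl_epochs transfer-learning epochs.
#' @param seed RNG seed.
#' @return list of class "adapt_config".
#' @export
adapt_config <- function(betas = c(0.5, 0.9), weight_decay = 1e-5,
                         lr_generator = 1e-5, lr_discriminator = 1e-4,
                         d_steps = 1400L, g_steps = 1L, clip_value = 0.05,
                         binding_proportion = 0.1, batch_size = 500L,
                         max_rounds = 10L, lr_head = 1e-3, tl_epochs = 3L,
                         disc_input = c("bottleneck", "all"),
                         early_stop = TRUE, seed = 1L) {
  disc_input <- match.arg(disc_input)
  stopifnot(lr_generator > 0, lr_discriminator > 0, clip_value > 0,
            binding_proportion >= 0, binding_proportion <= 1,
            d_steps >= 1, g_steps >= 1)
  structure(list(betas = betas, weight_decay = weight_decay,
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 d_steps = as.integer(d_steps), g_steps = as.integer(g_steps),
                 clip_value = clip_value,
                 binding_proportion = binding_proportion,
                 batch_size = as.integer(batch_size),
                 max_rounds = as.integer(max_rounds),
                 lr_head = lr_head, tl_epochs = as.integer(tl_epochs),
                 disc_input = disc_input, early_stop = early_stop,
                 seed = as.integer(seed)),
            class = "adapt_config")
}

#' @rdname adapt_config
#' @export
desk_adapt_config <- function(d_steps = 32L, g_steps = 4L, batch_size = 40L,
                              max_rounds = 6L, lr_generator = 5e-5,
                              lr_discriminator = 2e-4,
                              binding_proportion = 0.1,
                              disc_input = "all", seed = 1L, ...) {
  adapt_config(d_steps = d_steps, g_steps = g_steps, batch_size = batch_size,
               max_rounds = max_rounds, lr_generator = lr_generator,
               lr_discriminator = lr_discriminator,
               binding_proportion = binding_proportion,
               disc_input = disc_input, seed = seed, ...)
}

# assemble the discriminator input from generator features
.disc_in_channels <- function(cfg, disc_input) {
  if (disc_input == "bottleneck") cfg$conv_channels[3]
  else sum(cfg$conv_channels) + cfg$conv_channels[3]
}

.feats_to_disc <- function(feats, disc_input) {
  if (disc_input == "bottleneck") return(feats$bottleneck)
  T <- dim(feats$bottleneck)[2]
  p1 <- adaptive_meanpool_fwd(feats$skips$s1, T)$out
  p2 <- adaptive_meanpool_fwd(feats$skips$s2, T)$out
  abind2(abind2(p1, p2), abind2(feats$skips$s3, feats$bottleneck))
}

# split discriminator input gradient back into generator feature gradients
.disc_to_feats_grad <- function(dZ, feats, disc_input) {
  if (disc_input == "bottleneck") {
    return(list(ds1 = feats$skips$s1 * 0, ds2 = feats$skips$s2 * 0,
                ds3 = feats$skips$s3 * 0, dbottleneck = dZ))
  }
  T <- dim(feats$bottleneck)[2]
  c1 <- dim(feats$skips$s1)[1]
  c2 <- dim(feats$skips$s2)[1]
  c3 <- dim(feats$skips$s3)[1]
  d1 <- dZ[seq_len(c1), , , drop = FALSE]
  d2 <- dZ[c1 + seq_len(c2), , , drop = FALSE]
  d3 <- dZ[c1 + c2 + seq_len(c3), , , drop = FALSE]
  db <- dZ[c1 + c2 + c3 + seq_len(dim(feats$bottleneck)[1]), , , drop = FALSE]
  mp_bwd <- function(d, skip) {
    cache <- adaptive_meanpool_fwd(skip, T)$cache
    adaptive_meanpool_bwd(d, cache)$dx
  }
  list(ds1 = mp_bwd(d1, feats$skips$s1), ds2 = mp_bwd(d2, feats$skips$s2),
       ds3 = d3, dbottleneck = db)
}

#' Construct adversarial source/target pools
#'
#' Source pool: binding (positive) windows of the source species, species
#' label 1. Target pool: `(1 - p) * n_total` windows sampled uniformly from
#' the target training windows plus `p * n_total` target binding windows,
#' species label 0.
#'
#' @param target_ws target-species training window set (arbitrary windows).
#' @param target_binding_ws target-species binding windows (may be NULL when
#'   p = 0).
#' @param p binding proportion.
#' @param n_total target pool size.
#' @param seed RNG seed.
#' @return window set with meta$species_label = 0.
#' @export
build_target_data <- function(target_ws, target_binding_ws, p, n_total,
                              seed = 1L) {
  if (p > 0 && (is.null(target_binding_ws) ||
                nrow(target_binding_ws$meta) == 0)) {
    stop("binding_proportion > 0 but no target binding windows supplied")
  }
  set.seed(seed)
  n_bind <- round(p * n_total)
  n_rand <- n_total - n_bind
  parts <- list()
  if (n_rand > 0) {
    idx <- sample.int(nrow(target_ws$meta), n_rand,
                      replace = n_rand > nrow(target_ws$meta))
    parts <- c(parts, list(subset_window_set(target_ws, idx)))
  }
  if (n_bind > 0) {
    idx <- sample.int(nrow(target_binding_ws$meta), n_bind,
                      replace = n_bind > nrow(target_binding_ws$meta))
    parts <- c(parts, list(subset_window_set(target_binding_ws, idx)))
  }
  out <- if (length(parts) == 1) parts[[1]] else do.call(rbind_window_sets, parts)
  out$meta$species_label <- 0L
  out
}

.clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Adversarial losses
#'
#' Discriminator: binary cross-entropy with source features labelled 1 and
#' target features labelled 0 (natural log, batch means). Generator:
#' inverted-label loss on target features. Outputs at exactly 0 or 1 are
#' clamped to [1e-7, 1 - 1e-7].
#'
#' @param p_source discriminator outputs on source features.
#' @param p_target discriminator outputs on target features.
#' @return scalar loss.
#' @export
discriminator_loss <- function(p_source, p_target) {
  -mean(log(.clamp_prob(p_source))) - mean(log(1 - .clamp_prob(p_target)))
}

#' @rdname discriminator_loss
#' @export
generator_loss <- function(p_target) {
  -mean(log(.clamp_prob(p_target)))
}

# evaluate target model (G_t + frozen source predictor) on a labelled set
.target_model <- function(source_model, gt_params) {
  m <- source_model
  m$params[names(gt_params)] <- gt_params
  m
}

#' Adversarial adaptation of the target generator
#'
#' Implements the dual-path protocol: per round, `d_steps` discriminator
#' updates on source-vs-target bottleneck features (target generator
#' frozen), then `g_steps` generator updates on the inverted-label loss
#' (discriminator frozen). ADAM with the configured betas, weight decay and
#' elementwise gradient clipping on every update. Training stops when the
#' target-validation PR-AUC (through the frozen predictor) fails to improve
#' over the previous round, or at `max_rounds`; the best round's generator
#' is returned. The source generator and predictor are never modified.
#'
#' @param source_model trained source "nldnn_model".
#' @param source_ws source binding window set (species label 1).
#' @param target_ws target window set from [build_target_data()].
#' @param target_val optional labelled target validation set for the
#'   stopping criterion; when NULL, stopping falls back to the
#'   discriminator-loss plateau (|change| < 0.01).
#' @param config an [adapt_config()].
#' @return list(model = adapted target model, history, rounds_run,
#'   source_hash_ok).
#' @export
adapt <- function(source_model, source_ws, target_ws, target_val = NULL,
                  config = adapt_config()) {
  cfg <- source_model$config
  gn <- generator_param_names(source_model$params)
  gs <- source_model$params[gn]          # frozen
  gt <- source_model$params[gn]          # initialised from source
  hash0 <- param_hash(gs)
  T <- 600L %/% prod(cfg$pool_sizes)
  set.seed(config$seed)
  D <- build_discriminator(cfg, bottleneck_len = T,
                           in_channels = .disc_in_channels(cfg, config$disc_input),
                           seed = config$seed)
  opt_d <- adam_init(D$params)
  opt_g <- adam_init(gt)
  ns <- nrow(source_ws$meta)
  nt <- nrow(target_ws$meta)
  best <- list(metric = -Inf, gt = gt, round = 0L)
  prev_metric <- NA_real_
  prev_dloss <- NA_real_
  history <- data.frame()
  base_metric <- if (!is.null(target_val)) {
    evaluate_model(.target_model(source_model, gt), target_val)$prauc
  } else NA_real_
  # best-round selection runs over adaptation rounds only (the procedure
  # returns an adapted generator; comparison against the unadapted model is
  # the caller's analysis); the stopping rule compares consecutive rounds,
  # so the first comparison happens after round 2
  for (round in seq_len(config$max_rounds)) {
    dloss_acc <- 0
    for (s in seq_len(config$d_steps)) {
      si <- sample.int(ns, min(config$batch_size, ns))
      ti <- sample.int(nt, min(config$batch_size, nt))
      fs <- generator_forward(gs, cfg, source_ws$X[, , si, drop = FALSE], "eval")
      ft <- generator_forward(gt, cfg, target_ws$X[, , ti, drop = FALSE], "eval")
      Z <- abind2_batch(.feats_to_disc(fs, config$disc_input),
                        .feats_to_disc(ft, config$disc_input))
      dfw <- disc_forward(D, Z, "train")
      D$bn_state <- dfw$bn_state
      nb <- length(si)
      ps <- dfw$prob[seq_len(nb)]
      pt <- dfw$prob[nb + seq_along(ti)]
      dloss <- discriminator_loss(ps, pt)
      dloss_acc <- dloss_acc + dloss
      # d/dp of -mean(log ps) and -mean(log(1-pt))
      dprob <- c(-1 / (.clamp_prob(ps) * nb), 1 / ((1 - .clamp_prob(pt)) * length(ti)))
      dbw <- disc_backward(D, dfw$cache, dprob)
      st <- adam_step(D$params, dbw$grads, opt_d, config$lr_discriminator,
                      beta1 = config$betas[1], beta2 = config$betas[2],
                      weight_decay = config$weight_decay,
                      clip_value = config$clip_value)
      D$params <- st$params
      opt_d <- st$state
    }
    gloss_acc <- 0
    for (s in seq_len(config$g_steps)) {
      ti <- sample.int(nt, min(config$batch_size, nt))
      ft <- generator_forward(gt, cfg, target_ws$X[, , ti, drop = FALSE], "train")
      dfw <- disc_forward(D, .feats_to_disc(ft, config$disc_input), "train")
      pt <- dfw$prob                                   # D frozen: no update
      gloss <- generator_loss(pt)
      gloss_acc <- gloss_acc + gloss
      dprob <- -1 / (.clamp_prob(pt) * length(pt))
      dbw <- disc_backward(D, dfw$cache, dprob)
      gb <- generator_backward(.disc_to_feats_grad(dbw$dx, ft, config$disc_input),
                               ft$cache, gt, cfg)
      st <- adam_step(gt, gb$grads, opt_g, config$lr_generator,
                      beta1 = config$betas[1], beta2 = config$betas[2],
                      weight_decay = config$weight_decay,
                      clip_value = config$clip_value)
      gt <- st$params
      opt_g <- st$state
    }
    dloss_mean <- dloss_acc / config$d_steps
    gloss_mean <- gloss_acc / config$g_steps
    if (dloss_mean < 1e-4) {
      warning("discriminator collapse (loss < 1e-4) in round ", round,
              "; continuing")
    }
    metric <- NA_real_
    stop_now <- FALSE
    if (!is.null(target_val)) {
      metric <- evaluate_model(.target_model(source_model, gt), target_val)$prauc
      if (metric > best$metric) best <- list(metric = metric, gt = gt, round = round)
      if (!is.na(prev_metric) && metric <= prev_metric) stop_now <- TRUE
      prev_metric <- metric
    } else {
      best <- list(metric = NA_real_, gt = gt, round = round)
      if (!is.na(prev_dloss) && abs(dloss_mean - prev_dloss) < 0.01) stop_now <- TRUE
      prev_dloss <- dloss_mean
    }
    history <- rbind(history, data.frame(round = round, d_loss = dloss_mean,
                                         g_loss = gloss_mean,
                                         val_prauc = metric))
    if (stop_now && isTRUE(config$early_stop %||% TRUE)) break
  }
  stopifnot(param_hash(source_model$params[gn]) == hash0)   # G_s untouched
  list(model = .target_model(source_model, best$gt), history = history,
       rounds_run = nrow(history), best_round = best$round,
       base_val_prauc = base_metric,
       source_hash_ok = param_hash(source_model$params[gn]) == hash0)
}

# stack two (C,T,Bs)/(C,T,Bt) arrays along the batch dimension
abind2_batch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Transfer-learning baseline (species classifier head)
#'
#' Adds a classifier head (global average pooling, two fully-connected
#' layers with ReLU then sigmoid) on top of the source generator and
#' fine-tunes on species classification (source = 1, target = 0) with a
#' small generator learning rate and a larger head learning rate. The head
#' is discarded; the fine-tuned generator is returned combined with the
#' frozen predictor.
#'
#' @param source_model trained source "nldnn_model".
#' @param source_ws,target_ws window sets (species labels 1 and 0).
#' @param config an [adapt_config()] (uses lr_generator, lr_head,
#'   tl_epochs, batch_size, betas, weight_decay, clip_value).
#' @return list(model, history with per-epoch loss and accuracy).
#' @export
transfer_finetune <- function(source_model, source_ws, target_ws,
                              config = adapt_config()) {
  cfg <- source_model$config
  gn <- generator_param_names(source_model$params)
  gt <- source_model$params[gn]
  c3 <- cfg$conv_channels[3]
  hid <- cfg$disc_hidden
  set.seed(config$seed)
  head <- list(fc1_W = init_dense_w(hid, c3), fc1_b = numeric(hid),
               fc2_W = init_dense_w(1L, hid), fc2_b = numeric(1L))
  opt_g <- adam_init(gt)
  opt_h <- adam_init(head)
  X <- abind2_batch(source_ws$X, target_ws$X)
  y <- c(rep(1, nrow(source_ws$meta)), rep(0, nrow(target_ws$meta)))
  n <- length(y)
  history <- data.frame()
  for (epoch in seq_len(config$tl_epochs)) {
    perm <- sample.int(n)
    tot <- 0; acc <- 0; nb <- 0
    for (at in seq(1, n, by = config$batch_size)) {
      idx <- perm[at:min(n, at + config$batch_size - 1)]
      gf <- generator_forward(gt, cfg, X[, , idx, drop = FALSE], "train")
      gp <- global_meanpool_fwd(gf$bottleneck)
      f1 <- dense_fwd(gp$out, head$fc1_W, head$fc1_b)
      r1 <- relu_fwd(f1$out)
      f2 <- dense_fwd(r1$out, head$fc2_W, head$fc2_b)
      p <- .clamp_prob(sigmoid(as.numeric(f2$out)))
      yi <- y[idx]
      loss <- -mean(yi * log(p) + (1 - yi) * log(1 - p))
      tot <- tot + loss
      acc <- acc + mean((p > 0.5) == (yi == 1))
      nb <- nb + 1
      dlogit <- matrix((p - yi) / length(yi), 1)
      hb2 <- dense_bwd(dlogit, f2$cache, head$fc2_W)
      hr <- relu_bwd(hb2$dx, r1$cache)
      hb1 <- dense_bwd(hr$dx, f1$cache, head$fc1_W)
      hgrads <- list(fc1_W = hb1$dW, fc1_b = hb1$db,
                     fc2_W = hb2$dW, fc2_b = hb2$db)
      gpb <- global_meanpool_bwd(hb1$dx, gp$cache)
      gb <- generator_backward(list(ds1 = gf$skips$s1 * 0,
                                    ds2 = gf$skips$s2 * 0,
                                    ds3 = gf$skips$s3 * 0,
                                    dbottleneck = gpb$dx),
                               gf$cache, gt, cfg)
      sh <- adam_step(head, hgrads, opt_h, config$lr_head,
                      beta1 = config$betas[1], beta2 = config$betas[2],
                      weight_decay = config$weight_decay,
                      clip_value = config$clip_value)
      head <- sh$params; opt_h <- sh$state
      if (config$lr_generator > 0) {
        sg <- adam_step(gt, gb$grads, opt_g, config$lr_generator,
                        beta1 = config$betas[1], beta2 = config$betas[2],
                        weight_decay = config$weight_decay,
                        clip_value = config$clip_value)
        gt <- sg$params; opt_g <- sg$state
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = tot / nb,
                                         accuracy = acc / nb))
  }
  list(model = .target_model(source_model, gt), history = history, head = head)
}
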