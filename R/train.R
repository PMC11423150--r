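# Within-species supervised training: nucleotide-level MSE (+ L2) loss,
# rolling negative sampling without replacement at a fixed ratio, warm-up
# over random initialisations, ADAM with a step-decayed learning rate.

#' Training configuration
#'
#' Defaults follow the reference protocol (batch 500, 60 epochs, lr 1e-3
#' decayed by 0.9 every 10 epochs, 3x negatives per epoch);
#' [desk_train_config()] is the package's CPU-scale variant.
#'
#' @param batch_size windows per batch.
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param neg_ratio negatives sampled per positive per epoch.
#' @param alpha L2 penalty weight on model weights (biases and batch-norm
#'   parameters excluded).
#' @param warmup_inits random initialisations tried in the warm-up.
#' @param warmup_epochs epochs per warm-up candidate.
#' @param loss "mse" or "poisson" (exp-linked per-base Poisson deviance).
#' @param rc_augment reverse-complement each window with probability 1/2
#'   during training (targets reversed accordingly). Off by default.
#' @param seed RNG seed governing sampling and shuffling.
#' @return list of class "train_config".
#' @export
train_config <- function(batch_size = 500L, epochs = 60L, lr0 = 1e-3,
                         lr_decay = 0.9, lr_decay_every = 10L, neg_ratio = 3L,
                         alpha = 1e-6, warmup_inits = 3L, warmup_epochs = 2L,
                         loss = c("mse", "poisson"), rc_augment = FALSE,
                         seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(batch_size > 0, epochs > 0, lr0 > 0, lr_decay > 0,
            neg_ratio >= 1, alpha >= 0, warmup_inits >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 neg_ratio = as.integer(neg_ratio), alpha = alpha,
                 warmup_inits = as.integer(warmup_inits),
                 warmup_epochs = as.integer(warmup_epochs),
                 loss = loss, rc_augment = isTRUE(rc_augment),
                 seed = as.integer(seed)),
            class = "train_config")
}

# reverse-complement a one-hot batch in place: flip base rows and positions
.rc_batch <- function(X, tgt, which) {
  for (i in which) {
    X[1:4, , i] <- X[4:1, rev(seq_len(dim(X)[2])), i]
    if (dim(X)[1] == 5L) X[5L, , i] <- X[5L, rev(seq_len(dim(X)[2])), i]
    tgt[, i] <- rev(tgt[, i])
  }
  list(X = X, tgt = tgt)
}

#' @rdname train_config
#' @export
desk_train_config <- function(epochs = 36L, batch_size = 32L, lr0 = 2e-3,
                              alpha = 1e-4, rc_augment = TRUE, seed = 1L,
                              warmup_inits = 1L, ...) {
  train_config(batch_size = batch_size, epochs = epochs, lr0 = lr0,
               alpha = alpha, rc_augment = rc_augment,
               warmup_inits = warmup_inits, warmup_epochs = 2L, seed = seed,
               ...)
}

#' Nucleotide-level training loss
#'
#' MSE: mean over samples and positions of squared prediction error plus an
#' L2 penalty on the model weights. Poisson: mean per-base negative
#' log-likelihood (up to the data-only constant) of exp-linked predictions,
#' same penalty.
#'
#' @param pred L x N predictions.
#' @param true L x N true (log-scaled) coverage.
#' @param params optional model parameter list for the penalty.
#' @param alpha penalty weight.
#' @param loss "mse" or "poisson".
#' @return scalar loss.
#' @export
nldnn_loss <- function(pred, true, params = NULL, alpha = 0,
                       loss = c("mse", "poisson")) {
  loss <- match.arg(loss)
  if (!identical(dim(pred), dim(true)) && !identical(length(pred), length(true))) {
    stop("prediction/target shape mismatch")
  }
  base <- if (loss == "mse") {
    mean((pred - true)^2)
  } else {
    mean(exp(pred) - true * pred)
  }
  pen <- 0
  if (!is.null(params) && alpha > 0) {
    wn <- weight_param_names(params)
    pen <- alpha * sum(vapply(params[wn], function(w) sum(w * w), numeric(1)))
  }
  base + pen
}

# gradient of the data term w.r.t. predictions
.loss_grad <- function(pred, true, loss) {
  if (loss == "mse") 2 * (pred - true) / length(pred)
  else (exp(pred) - true) / length(pred)
}

#' Rolling negative sampler (without replacement)
#'
#' Iterates over a shuffled permutation of the negative pool; no negative is
#' reused until the pool is exhausted, then the pool is reshuffled.
#'
#' @param n_pool pool size.
#' @param seed RNG seed for the shuffles.
#' @return sampler state list.
#' @export
negative_sampler <- function(n_pool, seed = 1L) {
  set.seed(seed)
  list(perm = sample.int(n_pool), cursor = 0L, n_pool = n_pool)
}

#' @rdname negative_sampler
#' @param state sampler state.
#' @param n number of negatives to draw.
#' @return list(idx, state).
#' @export
sampler_draw <- function(state, n) {
  if (n > state$n_pool) {
    warning("negative pool smaller than one epoch's demand; reshuffling mid-epoch")
  }
  idx <- integer(0)
  while (length(idx) < n) {
    take <- min(n - length(idx), state$n_pool - state$cursor)
    if (take > 0) {
      idx <- c(idx, state$perm[state$cursor + seq_len(take)])
      state$cursor <- state$cursor + take
    }
    if (state$cursor >= state$n_pool) {
      state$perm <- sample.int(state$n_pool)   # ambient RNG, seeded per epoch
      state$cursor <- 0L
    }
  }
  list(idx = idx, state = state)
}

#' Batches for one epoch
#'
#' All positives once, plus `neg_ratio` times as many negatives drawn from
#' the rolling pool; the combined list is shuffled and cut into batches.
#' Deterministic given (config$seed, epoch).
#'
#' @param pos_idx indices of positive windows.
#' @param sampler sampler state over the negative pool indices.
#' @param neg_idx indices of the negative pool in the window set.
#' @param config train config.
#' @param epoch epoch number (1-based).
#' @return list(batches = list of index vectors, sampler = updated state).
#' @export
epoch_batches <- function(pos_idx, sampler, neg_idx, config, epoch) {
  set.seed(config$seed + 131L * epoch)
  dr <- sampler_draw(sampler, config$neg_ratio * length(pos_idx))
  all_idx <- c(pos_idx, neg_idx[dr$idx])
  all_idx <- all_idx[sample.int(length(all_idx))]
  nb <- ceiling(length(all_idx) / config$batch_size)
  batches <- split(all_idx, rep(seq_len(nb), each = config$batch_size,
                                length.out = length(all_idx)))
  list(batches = unname(batches), sampler = dr$state)
}

#' Learning rate schedule
#'
#' lr0 multiplied by `lr_decay` after every `lr_decay_every` epochs (epochs
#' 1..10 run at lr0, 11..20 at lr0*decay, ...).
#'
#' @param epoch 1-based epoch.
#' @param config train config.
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, config) {
  config$lr0 * config$lr_decay^((epoch - 1L) %/% config$lr_decay_every)
}

#' Train the nucleotide-level model
#'
#' ADAM with default moments, step-decayed learning rate, per-epoch
#' validation PR-AUC / Pearson via the max-coverage bridge; the
#' best-validation parameters are retained (falling back to the final epoch
#' when no validation set is given).
#'
#' @param model an "nldnn_model" (fresh or warm-started).
#' @param train_ws labelled training window set.
#' @param val_ws labelled validation window set or NULL.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list(model, history).
#' @export
train_nldnn <- function(model, train_ws, val_ws = NULL, config = train_config(),
                        verbose = FALSE) {
  pos_idx <- which(train_ws$meta$label == "positive")
  neg_idx <- which(train_ws$meta$label == "negative")
  stopifnot(length(pos_idx) > 0, length(neg_idx) > 0)
  sampler <- negative_sampler(length(neg_idx), seed = config$seed)
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        lr = numeric(0), val_prauc = numeric(0),
                        val_pearson = numeric(0))
  best <- list(prauc = -Inf, pearson = -Inf, params = model$params,
               bn_state = model$bn_state)
  wn <- weight_param_names(model$params)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    eb <- epoch_batches(pos_idx, sampler, neg_idx, config, epoch)
    sampler <- eb$sampler
    set.seed(config$seed + 977L * epoch)   # dropout stream
    tot <- 0
    nb <- 0
    for (bidx in eb$batches) {
      X <- train_ws$X[, , bidx, drop = FALSE]
      tgt <- train_ws$target[, bidx, drop = FALSE]
      if (config$rc_augment %||% FALSE) {
        flip <- which(stats::runif(length(bidx)) < 0.5)
        if (length(flip)) {
          rc <- .rc_batch(X, tgt, flip)
          X <- rc$X
          tgt <- rc$tgt
        }
      }
      fw <- nldnn_forward(model, X, "train")
      model$bn_state <- fw$bn_state
      l <- nldnn_loss(fw$pred, tgt, model$params, config$alpha, config$loss)
      if (!is.finite(l)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch mean pred ", mean(fw$pred), "); aborting")
      }
      bw <- nldnn_backward(model, fw, .loss_grad(fw$pred, tgt, config$loss))
      g <- bw$grads
      if (config$alpha > 0) {
        for (nm in wn) g[[nm]] <- g[[nm]] + 2 * config$alpha * model$params[[nm]]
      }
      st <- adam_step(model$params, g, opt, lr)
      model$params <- st$params
      opt <- st$state
      tot <- tot + l
      nb <- nb + 1
    }
    val_prauc <- NA_real_
    val_pearson <- NA_real_
    if (!is.null(val_ws) && nrow(val_ws$meta) > 0) {
      # degenerate validation sets (e.g. a single class) yield NA metrics
      # rather than aborting training
      ev <- tryCatch(evaluate_model(model, val_ws), error = function(e) NULL)
      if (!is.null(ev)) {
        val_prauc <- ev$prauc
        val_pearson <- ev$pearson_max
        if (val_prauc > best$prauc) {
          best <- list(prauc = val_prauc, pearson = val_pearson,
                       params = model$params, bn_state = model$bn_state)
        }
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tot / nb,
                                         lr = lr, val_prauc = val_prauc,
                                         val_pearson = val_pearson))
    if (verbose) {
      message(sprintf("epoch %d loss %.4f lr %.2e val PR-AUC %s", epoch,
                      tot / nb, lr,
                      ifelse(is.na(val_prauc), "-", sprintf("%.3f", val_prauc))))
    }
  }
  if (is.finite(best$prauc)) {
    model$params <- best$params
    model$bn_state <- best$bn_state
  }
  list(model = model, history = history)
}

#' Warm-up over random initialisations
#'
#' Trains `warmup_inits` freshly seeded models for `warmup_epochs` epochs
#' each and returns the one with the best validation PR-AUC (ties broken by
#' the lower seed).
#'
#' @param mconfig model config; candidate i uses seed `mconfig$seed + i - 1`.
#' @param train_ws,val_ws labelled window sets.
#' @param config train config.
#' @return list(model, val_prauc, seeds, chosen).
#' @export
warmup_select <- function(mconfig, train_ws, val_ws, config) {
  seeds <- mconfig$seed + seq_len(config$warmup_inits) - 1L
  wcfg <- config
  wcfg$epochs <- config$warmup_epochs
  best <- NULL
  scores <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    mc <- mconfig
    mc$seed <- seeds[i]
    cand <- build_nldnn(mc)
    tr <- train_nldnn(cand, train_ws, val_ws, wcfg)
    ev <- evaluate_model(tr$model, val_ws)
    scores[i] <- ev$prauc
    if (is.null(best) || scores[i] > best$val_prauc) {
      best <- list(model = tr$model, val_prauc = scores[i], seed = seeds[i])
    }
  }
  list(model = best$model, val_prauc = best$val_prauc, seeds = seeds,
       chosen = best$seed, scores = scores)
}

#' Train the sequence-level baseline
#'
#' Regresses the window maximum of true coverage with MSE under the same
#' sampling scheme.
#'
#' @param bl an "nldnn_baseline".
#' @param train_ws,val_ws labelled window sets.
#' @param config train config.
#' @return list(model, history).
#' @export
train_baseline <- function(bl, train_ws, val_ws = NULL, config = train_config()) {
  pos_idx <- which(train_ws$meta$label == "positive")
  neg_idx <- which(train_ws$meta$label == "negative")
  sampler <- negative_sampler(length(neg_idx), seed = config$seed)
  opt <- adam_init(bl$params)
  y_all <- window_max(train_ws$target)
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    eb <- epoch_batches(pos_idx, sampler, neg_idx, config, epoch)
    sampler <- eb$sampler
    set.seed(config$seed + 977L * epoch)
    tot <- 0; nb <- 0
    for (bidx in eb$batches) {
      X <- train_ws$X[, , bidx, drop = FALSE]
      y <- y_all[bidx]
      fw <- baseline_forward(bl, X, "train")
      l <- mean((fw$score - y)^2)
      bw <- baseline_backward(bl, fw$cache, 2 * (fw$score - y) / length(y))
      st <- adam_step(bl$params, bw$grads, opt, lr)
      bl$params <- st$params
      opt <- st$state
      tot <- tot + l; nb <- nb + 1
    }
    history <- c(history, tot / nb)
  }
  list(model = bl, history = history)
}
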