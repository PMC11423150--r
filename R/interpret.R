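# Interpretation: kernel-based motif discovery from the first convolution,
# gradient-times-input attribution, and TP/FP/FN site categorisation.

#' Kernel-based motif discovery
#'
#' For every positive test window: predict, locate the maximum, extract a
#' 60-bp window around it (clipped at edges), score each kernel-width
#' sub-region with the first convolutional layer (stride 1) and keep the
#' best-scoring sub-region per kernel when its activation exceeds
#' `act_frac` of that kernel's maximum over the set. Kept sub-regions are
#' aligned into a count matrix and converted to a PWM with pseudocount
#' 0.25; kernels with fewer supporting sub-regions than `min_support` are
#' dropped.
#'
#' @param model trained "nldnn_model".
#' @param ws window set of positive test windows.
#' @param extract_len extraction window around the predicted maximum.
#' @param min_support minimum supporting sub-regions per kernel.
#' @param act_frac activation threshold as a fraction of the kernel's
#'   maximum.
#' @param batch prediction batch size.
#' @return list of kernel motifs: list(kernel, n, pwm, ic).
#' @export
kernel_motifs <- function(model, ws, extract_len = 60L, min_support = 5L,
                          act_frac = 0.5, batch = 128L) {
  n <- nrow(ws$meta)
  if (n == 0) return(list())
  L <- dim(ws$X)[2]
  k1 <- model$config$conv_kernels[1]
  stopifnot(k1 <= extract_len)
  pred <- predict_window_set(model, ws, batch)
  # extraction windows around predicted maxima, clipped to the window
  subs <- array(0, c(4L, extract_len, n))
  for (i in seq_len(n)) {
    ctr <- which.max(pred[, i])
    s0 <- min(max(1L, ctr - extract_len %/% 2L), L - extract_len + 1L)
    subs[, , i] <- ws$X[1:4, s0:(s0 + extract_len - 1L), i]
  }
  # first-layer activations of every sub-region, stride 1, valid positions
  W1 <- model$params$enc1_W[, seq_len(4L * k1), drop = FALSE]
  nk <- nrow(W1)
  npos <- extract_len - k1 + 1L
  best_pos <- matrix(0L, nk, n)
  best_act <- matrix(-Inf, nk, n)
  for (i in seq_len(n)) {
    M <- cpp_im2col(subs[, , i, drop = FALSE], 4L, extract_len, 1L, k1)
    A <- W1 %*% M                      # nk x extract_len ('same' positions)
    # valid sub-regions start at 1..npos; 'same' output col for start s is
    # s + floor((k1-1)/2)
    off <- (k1 - 1L) %/% 2L
    Av <- A[, off + seq_len(npos), drop = FALSE]
    best_pos[, i] <- max.col(Av, ties.method = "first")
    best_act[, i] <- Av[cbind(seq_len(nk), best_pos[, i])]
  }
  out <- list()
  for (kk in seq_len(nk)) {
    thr <- act_frac * max(best_act[kk, ])
    keep <- which(best_act[kk, ] > thr)
    if (length(keep) < min_support) next
    counts <- matrix(0.25, 4L, k1, dimnames = list(.onehot_rows, NULL))
    for (i in keep) {
      s <- best_pos[kk, i]
      counts <- counts + subs[, s:(s + k1 - 1L), i]
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    ic <- 2 + colSums(ifelse(pwm > 0, pwm * log2(pwm), 0))
    out[[length(out) + 1L]] <- list(kernel = kk, n = length(keep),
                                    pwm = pwm, ic = ic)
  }
  out
}

#' Gradient-times-input attribution
#'
#' Appends a max over the per-base outputs to get a scalar head, takes the
#' gradient of that scalar with respect to the one-hot input, multiplies
#' elementwise by the input and sums over channels: a per-base contribution
#' track. Zero columns (N bases) get zero attribution.
#'
#' @param model an "nldnn_model".
#' @param X one-hot window: matrix (C, L) or array (C, L, 1).
#' @return numeric length-L contribution vector.
#' @export
attribution <- function(model, X) {
  if (length(dim(X)) == 2) X <- array(X, c(dim(X), 1L))
  fw <- nldnn_forward(model, X, "eval")
  dpred <- fw$pred * 0
  dpred[which.max(fw$pred[, 1]), 1] <- 1
  bw <- nldnn_backward(model, fw, dpred, want_dx = TRUE)
  colSums(bw$dx[, , 1] * X[, , 1])
}

# min-max scale to [-1, 1] then sigmoid to (0, 1); constant vectors map to
# sigmoid(0) = 0.5
.scale_track <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    message("constant track: scaled value defined as 0.5")
    return(rep(0.5, length(x)))
  }
  sigmoid(2 * (x - r[1]) / (r[2] - r[1]) - 1)
}

#' Categorise predicted binding sites
#'
#' Both tracks are min-max scaled to [-1, 1] and squashed through a sigmoid
#' to (0, 1); the per-window scaled maxima P (prediction) and T (truth)
#' are classified as: TP when P > 0.7 and T > 0.7; FP when P > 0.5,
#' T < 0.5 and |P - T| > 0.5; FN when P < 0.5, T > 0.5 and |P - T| > 0.5;
#' otherwise "other". The rules are mutually exclusive.
#'
#' @param pred per-base predictions: vector (one window) or L x B matrix.
#' @param true matching true coverage.
#' @param scope "window" scales each window's track separately; "global"
#'   scales over the concatenated tracks.
#' @return character vector of categories (one per window) with attributes
#'   P and T.
#' @export
categorize_sites <- function(pred, true, scope = c("global", "window")) {
  scope <- match.arg(scope)
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1)
  if (is.null(dim(true))) true <- matrix(true, ncol = 1)
  stopifnot(identical(dim(pred), dim(true)))
  if (scope == "global") {
    P <- window_max(matrix(.scale_track(as.vector(pred)), nrow(pred)))
    T <- window_max(matrix(.scale_track(as.vector(true)), nrow(true)))
  } else {
    P <- apply(pred, 2, function(v) max(.scale_track(v)))
    T <- apply(true, 2, function(v) max(.scale_track(v)))
  }
  cat <- rep("other", length(P))
  cat[P > 0.5 & T < 0.5 & abs(P - T) > 0.5] <- "FP"
  cat[P < 0.5 & T > 0.5 & abs(P - T) > 0.5] <- "FN"
  cat[P > 0.7 & T > 0.7] <- "TP"
  structure(cat, P = P, T = T)
}

#' @rdname categorize_sites
#' @param P,T already-scaled window maxima in (0, 1).
#' @return category string.
#' @export
categorize_pt <- function(P, T) {
  if (P > 0.7 && T > 0.7) return("TP")
  if (P > 0.5 && T < 0.5 && abs(P - T) > 0.5) return("FP")
  if (P < 0.5 && T > 0.5 && abs(P - T) > 0.5) return("FN")
  "other"
}
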