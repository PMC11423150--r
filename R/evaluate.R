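# The max-coverage bridge and metric protocols.
#
# Nucleotide-level models emit a per-base vector; the window maximum of that
# vector is the scalar binding-strength score that makes them directly
# comparable with sequence-level models under PR-AUC / ROC-AUC / Pearson.

#' Window maximum score
#'
#' @param pred per-base prediction: numeric vector or L x B matrix.
#' @return scalar or length-B vector of window maxima.
#' @export
window_max <- function(pred) {
  if (is.matrix(pred)) apply(pred, 2, max) else max(pred)
}

#' Precision-recall and ROC AUC
#'
#' PR-AUC by step interpolation over tie-grouped thresholds (equivalent to
#' average precision with ties handled jointly); ROC-AUC as the normalised
#' Mann-Whitney U statistic with midranks for ties.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 (or logical) labels.
#' @return list(prauc, rocauc).
#' @export
classification_metrics <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) {
    stop("classification metrics undefined: both classes must be present")
  }
  # ROC-AUC via midranks
  r <- rank(scores)
  rocauc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  # PR-AUC: descending threshold sweep, ties grouped
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_last <- which(diff(s) != 0)
  cut <- c(grp_last, length(s))        # last index of each threshold group
  tp <- cumsum(y)[cut]
  fp <- (seq_along(s) - cumsum(y))[cut]
  prec <- tp / (tp + fp)
  rec <- tp / np
  prev_rec <- c(0, rec[-length(rec)])
  prauc <- sum((rec - prev_rec) * prec)
  list(prauc = prauc, rocauc = rocauc)
}

#' Regression (fit) metrics on positive windows
#'
#' `positives_max` correlates per-window true vs predicted maxima over
#' positive windows; `all_nucleotides` correlates the concatenated per-base
#' values of positive windows.
#'
#' @param pred L x B matrix of predictions for positive windows.
#' @param true matching matrix of true (log-scaled) coverage.
#' @param scope "positives_max" or "all_nucleotides".
#' @param method "pearson" or "spearman".
#' @return correlation coefficient.
#' @export
fit_metrics <- function(pred, true,
                        scope = c("positives_max", "all_nucleotides"),
                        method = c("pearson", "spearman")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  a <- if (scope == "positives_max") window_max(pred) else as.vector(pred)
  b <- if (scope == "positives_max") window_max(true) else as.vector(true)
  if (length(a) < 3) stop("need at least 3 points for a correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(a, b, method = method)
}

#' Binding strength from reads vs peak coverage maxima
#'
#' Per-peak read count (any >= 1-base overlap counts), log10(1 + count)
#' strength, correlated with the per-peak maximum of the coverage track.
#'
#' @param reads data.frame (chrom, start, end) of read alignments.
#' @param peaks data.frame (chrom, start, end).
#' @param coverage named list of per-base coverage used for the per-peak
#'   maxima.
#' @return list(pearson, strength, peak_max).
#' @export
binding_strength_correlation <- function(reads, peaks, coverage) {
  if (nrow(peaks) == 0) stop("no peaks")
  counts <- GenomicRanges::countOverlaps(.gr0(peaks), .gr0(reads),
                                         minoverlap = 1L)
  if (all(counts == 0)) stop("no reads overlap any peak; strength undefined")
  strength <- log10(1 + counts)
  peak_max <- vapply(seq_len(nrow(peaks)), function(i) {
    max(coverage[[peaks$chrom[i]]][(peaks$start[i] + 1L):peaks$end[i]])
  }, numeric(1))
  list(pearson = stats::cor(strength, peak_max),
       strength = strength, peak_max = peak_max)
}

# batched prediction over a window set
predict_window_set <- function(model, ws, batch = 128L) {
  n <- dim(ws$X)[3]
  L <- dim(ws$X)[2]
  pred <- matrix(0, L, n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch - 1L)
    pred[, idx] <- nldnn_predict(model, ws$X[, , idx, drop = FALSE])
    at <- at + batch
  }
  pred
}

#' Evaluate a model on a labelled window set
#'
#' Classification metrics use window maxima of predicted vs true coverage
#' (the bridge); fit metrics are computed on positive windows only.
#'
#' @param model an "nldnn_model" (or "nldnn_baseline").
#' @param ws labelled window set.
#' @param batch prediction batch size.
#' @return list(prauc, rocauc, pearson_max, pearson_nt, n_pos, n_neg).
#' @export
evaluate_model <- function(model, ws, batch = 128L) {
  labels <- as.integer(ws$meta$label == "positive")
  if (inherits(model, "nldnn_baseline")) {
    scores <- baseline_forward(model, ws$X, "eval")$score
    pos <- labels == 1L
    cm <- classification_metrics(scores, labels)
    pm <- stats::cor(scores[pos], window_max(ws$target[, pos, drop = FALSE]))
    return(list(prauc = cm$prauc, rocauc = cm$rocauc,
                pearson_max = pm, pearson_nt = NA_real_,
                n_pos = sum(pos), n_neg = sum(!pos)))
  }
  pred <- predict_window_set(model, ws, batch)
  scores <- window_max(pred)
  cm <- classification_metrics(scores, labels)
  pos <- labels == 1L
  # fit metrics are NA (not an error) on degenerate sets, e.g. too few
  # positives or constant early-training predictions
  safe_fit <- function(scope) {
    tryCatch(fit_metrics(pred[, pos, drop = FALSE],
                         ws$target[, pos, drop = FALSE], scope),
             error = function(e) NA_real_)
  }
  list(prauc = cm$prauc,
       rocauc = cm$rocauc,
       pearson_max = safe_fit("positives_max"),
       pearson_nt = safe_fit("all_nucleotides"),
       n_pos = sum(pos), n_neg = sum(!pos))
}
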