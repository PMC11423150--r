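# Binding-region localization: scan a chromosome in non-overlapping
# windows, select the top fraction by predicted maximum, and score the
# selection by peak intersection and by motif-instance content under an
# exact PWM p-value null.

#' Scan a chromosome with a trained model
#'
#' Non-overlapping windows tile the chromosome (final partial window
#' dropped); each window records its predicted maximum and the genomic
#' position of that maximum (leftmost on ties).
#'
#' @param model an "nldnn_model".
#' @param genome genome assembly.
#' @param chrom chromosome name.
#' @param window_len window length.
#' @param batch prediction batch size.
#' @return data.frame (chrom, start, end, max_value, max_pos) of class
#'   "scan_result".
#' @export
scan_chromosome <- function(model, genome, chrom, window_len = 600L,
                            batch = 128L) {
  len <- nchar(genome[[chrom]])
  stopifnot(len >= window_len)
  starts <- seq.int(0L, len - window_len, by = window_len)
  seqs <- vapply(starts, function(s) {
    substr(genome[[chrom]], s + 1L, s + window_len)
  }, character(1))
  X <- .encode_onehot(seqs)
  n <- length(starts)
  mx <- numeric(n)
  mp <- integer(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch - 1L)
    pred <- nldnn_predict(model, X[, , idx, drop = FALSE])
    mx[idx] <- apply(pred, 2, max)
    mp[idx] <- apply(pred, 2, which.max)        # leftmost tie
    at <- at + batch
  }
  structure(data.frame(chrom = chrom, start = starts,
                       end = starts + window_len,
                       max_value = mx, max_pos = starts + mp - 1L),
            class = c("scan_result", "data.frame"))
}

#' Select the top fraction of scanned windows
#'
#' k = max(1, floor(fraction * n)) windows with the highest predicted
#' maxima; ties at the cutoff resolved in favour of the leftmost start.
#'
#' @param scan a [scan_chromosome()] result (or several row-bound).
#' @param fraction fraction of windows to keep.
#' @return data.frame (chrom, start, end, max_value) of the selected
#'   regions.
#' @export
select_top_regions <- function(scan, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(scan)
  k <- max(1L, floor(fraction * n))
  o <- order(-scan$max_value, scan$start)
  out <- scan[o[seq_len(k)], c("chrom", "start", "end", "max_value")]
  rownames(out) <- NULL
  out
}

#' Fraction of regions intersecting peaks
#'
#' A region counts as 1 when it overlaps at least one peak by at least one
#' base.
#'
#' @param regions data.frame (chrom, start, end).
#' @param peaks data.frame (chrom, start, end).
#' @return fraction in [0, 1].
#' @export
intersect_ratio <- function(regions, peaks) {
  stopifnot(nrow(regions) > 0)
  if (is.null(peaks) || nrow(peaks) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(.gr0(regions), .gr0(peaks),
                                       minoverlap = 1L)
  mean(hits > 0)
}

# ---- exact PWM p-values -----------------------------------------------------

#' Exact PWM score threshold by dynamic programming
#'
#' Per-position log-odds scores (log2 of PWM over background, pseudocount
#' applied to degenerate columns) are discretised at `granularity`; the
#' exact null distribution of the total score of a random background
#' sequence is built by convolution over positions. The returned threshold
#' is the smallest discretised score whose tail probability is below
#' `alpha`, together with that achieved tail probability.
#'
#' @param pwm 4 x W probability matrix (rows A, C, G, T).
#' @param bg background base frequencies.
#' @param alpha nominal p-value threshold.
#' @param granularity score discretisation step.
#' @return list(threshold, achieved_alpha, lo = discretised integer
#'   log-odds matrix, granularity).
#' @export
pwm_score_threshold <- function(pwm, bg = rep(0.25, 4), alpha = 1e-4,
                                granularity = 1e-3) {
  if (any(pwm == 0)) {
    message("degenerate PWM column: applying pseudocount 1e-3")
    pwm <- pwm + 1e-3
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
  }
  lo <- round(log2(pwm / bg) / granularity)
  W <- ncol(lo)
  off <- -apply(lo, 2, min)                 # shift each column nonnegative
  span <- sum(apply(lo, 2, max) + off)
  dist <- numeric(span + 1L)                # P(shifted score = s), s = 0..span
  dist[1] <- 1
  upto <- 0L
  for (j in seq_len(W)) {
    nd <- numeric(span + 1L)
    sj <- lo[, j] + off[j]
    for (b in 1:4) {
      idx <- seq_len(upto + 1L) + sj[b]
      nd[idx] <- nd[idx] + dist[seq_len(upto + 1L)] * bg[b]
    }
    dist <- nd
    upto <- upto + max(sj)
  }
  tail_p <- rev(cumsum(rev(dist)))          # P(shifted score >= s)
  shift <- sum(off)
  ok <- which(tail_p < alpha)
  if (length(ok) == 0) stop("no achievable score has p-value below alpha")
  t_shifted <- min(ok) - 1L                 # 0-based shifted score
  list(threshold = t_shifted - shift,       # integer units of granularity
       achieved_alpha = tail_p[t_shifted + 1L],
       lo = lo, granularity = granularity, bg = bg)
}

# integer log-odds scores of every position of a one-hot matrix (4 x L),
# forward strand; N columns score -Inf
.pwm_scan_scores <- function(X1, lo) {
  L <- ncol(X1)
  W <- ncol(lo)
  if (L < W) return(numeric(0))
  sc <- numeric(L - W + 1L)
  covered <- numeric(L - W + 1L)
  for (j in seq_len(W)) {
    cols <- j:(L - W + j)
    sc <- sc + colSums(lo[, j] * X1[, cols, drop = FALSE])
    covered <- covered + colSums(X1[, cols, drop = FALSE])
  }
  sc[covered < W] <- -Inf                   # windows containing N
  sc
}

#' Scan sequences for significant motif instances
#'
#' Both strands are scanned; a hit is any position whose exact p-value is
#' below the threshold used to build `thr`.
#'
#' @param sequence character sequence.
#' @param thr result of [pwm_score_threshold()].
#' @return integer count of hit positions (both strands).
#' @export
pwm_count_hits <- function(sequence, thr) {
  X1 <- .encode_onehot(sequence)[, , 1L]
  lo <- thr$lo
  rc <- lo[4:1, ncol(lo):1, drop = FALSE]
  sum(.pwm_scan_scores(X1, lo) >= thr$threshold) +
    sum(.pwm_scan_scores(X1, rc) >= thr$threshold)
}

#' Fraction of regions containing a significant motif instance
#'
#' @param regions data.frame (chrom, start, end).
#' @param genome genome assembly.
#' @param pwm 4 x W probability matrix.
#' @param pvalue_threshold exact p-value cutoff.
#' @param bg background base frequencies.
#' @return fraction of regions with at least one hit on either strand.
#' @export
motif_instance_ratio <- function(regions, genome, pwm,
                                 pvalue_threshold = 1e-4,
                                 bg = rep(0.25, 4)) {
  stopifnot(ncol(pwm) <= min(regions$end - regions$start))
  thr <- pwm_score_threshold(pwm, bg, alpha = pvalue_threshold)
  hits <- vapply(seq_len(nrow(regions)), function(i) {
    s <- substr(genome[[regions$chrom[i]]], regions$start[i] + 1L,
                regions$end[i])
    pwm_count_hits(s, thr) > 0
  }, logical(1))
  mean(hits)
}
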