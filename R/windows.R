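# Genome -> labelled, encoded, split training windows.
#
# Windows are data.frames (chrom, start, end, gc, ...) with 0-based
# half-open coordinates. Encoded window sets are lists:
#   list(meta = data.frame, X = array(C, L, n), target = matrix(L, n))
# Overlap queries go through GenomicRanges.

#' Enumerate candidate windows along a genome
#'
#' Fixed-length windows at a regular offset; any window overlapping an
#' exclusion interval (e.g. a blacklist) by at least one base is dropped.
#' Per chromosome the full count is floor((len - window_len)/offset) + 1
#' before exclusions; chromosomes shorter than `window_len` yield none.
#'
#' @param genome genome assembly (named list of sequences).
#' @param window_len window length in bases.
#' @param offset start-to-start spacing in bases.
#' @param exclude optional data.frame (chrom, start, end) of intervals to
#'   avoid.
#' @return data.frame (chrom, start, end, gc).
#' @export
enumerate_windows <- function(genome, window_len = 600L, offset = 100L,
                              exclude = NULL) {
  stopifnot(window_len > 0, offset > 0)
  out <- list()
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    if (len < window_len) {
      message("chromosome ", chrom, " shorter than window length; skipped")
      next
    }
    starts <- seq.int(0L, len - window_len, by = offset)
    # GC fraction for every window via a sliding view over the sequence
    gcall <- Biostrings::letterFrequencyInSlidingView(
      Biostrings::DNAString(genome[[chrom]]), window_len, c("G", "C"))
    gc <- (gcall[starts + 1L, 1] + gcall[starts + 1L, 2]) / window_len
    out[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + window_len, gc = gc)
  }
  win <- do.call(rbind, out)
  if (is.null(win)) {
    win <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gc = numeric(0))
  }
  rownames(win) <- NULL
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(win) > 0) {
    hits <- GenomicRanges::countOverlaps(.gr0(win), .gr0(exclude),
                                         minoverlap = 1L)
    win <- win[hits == 0L, , drop = FALSE]
    rownames(win) <- NULL
  }
  win
}

#' Label windows by peak overlap
#'
#' A window is positive when its overlap with the union of peaks exceeds
#' `min_overlap_ratio` of its length, negative when it does not touch any
#' peak, and discarded (neither set) for overlaps in between.
#'
#' @param windows data.frame from [enumerate_windows()].
#' @param peaks data.frame (chrom, start, end).
#' @param min_overlap_ratio strict lower bound for the positive overlap
#'   fraction.
#' @return list(positives, negative_pool) of window data.frames.
#' @export
label_windows <- function(windows, peaks, min_overlap_ratio = 0.2) {
  stopifnot(min_overlap_ratio > 0, min_overlap_ratio <= 1)
  if (nrow(windows) == 0) {
    return(list(positives = windows, negative_pool = windows))
  }
  wlen <- windows$end - windows$start
  ovl <- numeric(nrow(windows))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    pk <- GenomicRanges::reduce(.gr0(peaks))
    wgr <- .gr0(windows)
    h <- GenomicRanges::findOverlaps(wgr, pk, minoverlap = 1L)
    if (length(h) > 0) {
      inter <- GenomicRanges::pintersect(wgr[S4Vectors::queryHits(h)],
                                         pk[S4Vectors::subjectHits(h)])
      ob <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(h), sum)
      ovl[as.integer(names(ob))] <- ob
    }
  }
  pos <- windows[ovl / wlen > min_overlap_ratio, , drop = FALSE]
  neg <- windows[ovl == 0, , drop = FALSE]
  rownames(pos) <- NULL
  rownames(neg) <- NULL
  list(positives = pos, negative_pool = neg)
}

#' GC-matched negative selection
#'
#' GC fractions are histogrammed into equal-width bins over [0, 1]; negatives
#' are sampled without replacement per bin proportionally to the positive bin
#' counts. Underfull bins borrow from the nearest adjacent bins with a
#' warning.
#'
#' @param positives positive windows (with gc column).
#' @param negative_pool candidate negatives.
#' @param n_select number of negatives wanted; defaults to 3x the positives.
#' @param bins number of equal-width GC bins.
#' @param seed RNG seed.
#' @return data.frame of selected negatives.
#' @export
gc_match_negatives <- function(positives, negative_pool,
                               n_select = 3L * nrow(positives),
                               bins = 20L, seed = 1L) {
  if (nrow(negative_pool) == 0) stop("negative pool is empty")
  if (n_select <= 0) return(negative_pool[0, , drop = FALSE])
  if (n_select >= nrow(negative_pool)) {
    warning("negative pool (", nrow(negative_pool),
            ") smaller than request (", n_select, "); returning all")
    return(negative_pool)
  }
  set.seed(seed)
  brk <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(gc) pmin(bins, pmax(1L, findInterval(gc, brk,
                                                          rightmost.closed = TRUE)))
  pos_bin <- tabulate(bin_of(positives$gc), nbins = bins)
  want <- round(n_select * pos_bin / sum(pos_bin))
  # fix rounding drift
  drift <- n_select - sum(want)
  if (drift != 0) {
    o <- order(pos_bin, decreasing = TRUE)
    want[o[1]] <- want[o[1]] + drift
  }
  neg_bin <- bin_of(negative_pool$gc)
  chosen <- integer(0)
  deficit <- integer(bins)
  for (b in seq_len(bins)) {
    avail <- which(neg_bin == b)
    take <- min(want[b], length(avail))
    if (take > 0) chosen <- c(chosen, sample(avail, take))
    deficit[b] <- want[b] - take
  }
  if (sum(deficit) > 0) {
    warning("GC bins underfull; borrowing ", sum(deficit),
            " negatives from adjacent bins")
    remaining <- setdiff(seq_len(nrow(negative_pool)), chosen)
    for (b in which(deficit > 0)) {
      need <- deficit[b]
      for (dist in seq_len(bins)) {
        if (need == 0) break
        for (nb in unique(pmin(bins, pmax(1L, c(b - dist, b + dist))))) {
          if (need == 0) break
          avail <- remaining[neg_bin[remaining] == nb]
          take <- min(need, length(avail))
          if (take > 0) {
            pickd <- if (length(avail) == 1) avail else sample(avail, take)
            chosen <- c(chosen, pickd)
            remaining <- setdiff(remaining, pickd)
            need <- need - take
          }
        }
      }
    }
  }
  out <- negative_pool[sort(chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.onehot_rows <- c("A", "C", "G", "T")

# one-hot encode a vector of equal-length sequences -> array (4, L, n)
.encode_onehot <- function(seqs, extra_rows = 0L) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  X <- array(0, c(4L + extra_rows, L, n))
  chars <- strsplit(seqs, "")
  for (i in seq_len(n)) {
    m <- match(chars[[i]], .onehot_rows)
    bad <- is.na(m) & chars[[i]] != "N"
    if (any(bad)) {
      stop("non-ACGTN character '", chars[[i]][which(bad)[1]],
           "' at position ", which(bad)[1], " of window ", i)
    }
    ok <- which(!is.na(m))
    X[cbind(m[ok], ok, i)] <- 1
  }
  X
}

#' Encode a single window
#'
#' One-hot encodes the sequence (rows A, C, G, T; N becomes an all-zero
#' column) and builds the per-base regression target: log10(1 + raw
#' coverage) for positive windows, zeros for negatives.
#'
#' @param sequence window sequence (A/C/G/T/N).
#' @param coverage raw per-base coverage over the window, or NULL for a
#'   negative window.
#' @param accessibility optional per-base accessibility over the window;
#'   appended as a 5th input row.
#' @return list(onehot, target).
#' @export
encode_window <- function(sequence, coverage = NULL, accessibility = NULL) {
  L <- nchar(sequence)
  X <- .encode_onehot(sequence, extra_rows = if (is.null(accessibility)) 0L else 1L)
  if (!is.null(accessibility)) X[5L, , 1L] <- accessibility
  target <- if (is.null(coverage)) numeric(L) else log10(1 + coverage)
  list(onehot = X[, , 1L], target = target)
}

#' Encode a set of labelled windows
#'
#' @param windows data.frame with chrom, start, end and a `label` column
#'   ("positive"/"negative").
#' @param genome genome assembly.
#' @param coverage named list of per-base raw coverage (required when any
#'   window is positive).
#' @param accessibility optional named list of per-base accessibility.
#' @return window set: list(meta, X, target).
#' @export
encode_windows <- function(windows, genome, coverage = NULL,
                           accessibility = NULL) {
  n <- nrow(windows)
  L <- if (n > 0) windows$end[1] - windows$start[1] else 0L
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- substr(genome[[windows$chrom[i]]], windows$start[i] + 1L,
                      windows$end[i])
  }
  C <- if (is.null(accessibility)) 4L else 5L
  X <- if (n > 0) .encode_onehot(seqs, extra_rows = C - 4L) else
    array(0, c(C, L, 0L))
  target <- matrix(0, L, n)
  for (i in seq_len(n)) {
    if (identical(windows$label[i], "positive")) {
      raw <- coverage[[windows$chrom[i]]][(windows$start[i] + 1L):windows$end[i]]
      target[, i] <- log10(1 + raw)
    }
    if (C == 5L) {
      X[5L, , i] <- accessibility[[windows$chrom[i]]][(windows$start[i] + 1L):windows$end[i]]
    }
  }
  structure(list(meta = windows, X = X, target = target), class = "window_set")
}

#' Subset a window set
#'
#' @param ws window set.
#' @param idx integer or logical index into the windows.
#' @return window set.
#' @export
subset_window_set <- function(ws, idx) {
  meta <- ws$meta[idx, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(meta = meta, X = ws$X[, , idx, drop = FALSE],
                 target = ws$target[, idx, drop = FALSE]),
            class = "window_set")
}

#' Concatenate window sets
#' @param ... window sets with identical window length and channels.
#' @return window set.
#' @export
rbind_window_sets <- function(...) {
  parts <- list(...)
  meta <- do.call(rbind, lapply(parts, function(p) p$meta))
  rownames(meta) <- NULL
  n <- sum(vapply(parts, function(p) dim(p$X)[3], numeric(1)))
  d <- dim(parts[[1]]$X)
  X <- array(0, c(d[1], d[2], n))
  target <- matrix(0, d[2], n)
  at <- 0L
  for (p in parts) {
    k <- dim(p$X)[3]
    if (k > 0) {
      X[, , at + seq_len(k)] <- p$X
      target[, at + seq_len(k)] <- p$target
    }
    at <- at + k
  }
  structure(list(meta = meta, X = X, target = target), class = "window_set")
}

#' Split windows by chromosome
#'
#' Every window goes to exactly one of train/val/test by chromosome
#' membership; windows on chromosomes not listed anywhere go to train.
#'
#' @param windows window data.frame or window set.
#' @param split list(train, val, test) of disjoint chromosome vectors.
#' @return list(train, val, test) of the same type as the input.
#' @export
split_by_chromosome <- function(windows, split) {
  sets <- list(train = split$train %||% character(0),
               val = split$val %||% character(0),
               test = split$test %||% character(0))
  all_listed <- unlist(sets)
  if (anyDuplicated(all_listed)) {
    stop("split chromosome lists overlap: ",
         paste(unique(all_listed[duplicated(all_listed)]), collapse = ", "))
  }
  meta <- if (inherits(windows, "window_set")) windows$meta else windows
  assign_to <- ifelse(meta$chrom %in% sets$val, "val",
                      ifelse(meta$chrom %in% sets$test, "test", "train"))
  pick <- function(grp) {
    idx <- which(assign_to == grp)
    if (inherits(windows, "window_set")) subset_window_set(windows, idx)
    else { out <- meta[idx, , drop = FALSE]; rownames(out) <- NULL; out }
  }
  list(train = pick("train"), val = pick("val"), test = pick("test"))
}
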