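# Variant-effect scoring, TF-specific SNP classification, causal-SNP
# prioritisation and in-silico saturation mutagenesis.

.window_for_variant <- function(genome, chrom, pos, window_len) {
  len <- nchar(genome[[chrom]])
  if (len < window_len) stop("chromosome ", chrom, " shorter than the window")
  start <- pos - window_len %/% 2L             # 0-based window start
  shifted <- FALSE
  if (start < 0) { start <- 0L; shifted <- TRUE }
  if (start + window_len > len) { start <- len - window_len; shifted <- TRUE }
  list(start = start, offset = pos - start, shifted = shifted)
}

#' Variant effect score
#'
#' Builds reference and alternative windows centred on the variant (shifted
#' at chromosome edges), predicts both, and sums the per-base differences
#' over the neighbourhood D = variant position +/- `D_radius` bases:
#' absolute differences in "abs" mode (classification-style effects), raw
#' differences in "signed" mode (reporter-assay-style effects). For a
#' sequence-level baseline the score is the (absolute) difference of the
#' scalar outputs.
#'
#' @param model "nldnn_model" or "nldnn_baseline".
#' @param genome genome assembly.
#' @param variants data.frame (chrom, pos, ref, alt, ...).
#' @param window_len window length.
#' @param D_radius neighbourhood radius in bases.
#' @param mode "abs" or "signed".
#' @param batch prediction batch size.
#' @return numeric vector of effect values (one per variant).
#' @export
effect_scores <- function(model, genome, variants, window_len = 600L,
                          D_radius = 100L, mode = c("abs", "signed"),
                          batch = 128L) {
  mode <- match.arg(mode)
  n <- nrow(variants)
  if (n == 0) return(numeric(0))
  seqs <- character(2L * n)
  offs <- integer(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    w <- .window_for_variant(genome, v$chrom, v$pos, window_len)
    s <- substr(genome[[v$chrom]], w$start + 1L, w$start + window_len)
    refbase <- substr(s, w$offset + 1L, w$offset + 1L)
    if (refbase != v$ref) {
      stop("ref allele mismatch at ", v$chrom, ":", v$pos,
           " (genome has ", refbase, ", table has ", v$ref, ")")
    }
    alt <- s
    substr(alt, w$offset + 1L, w$offset + 1L) <- v$alt
    seqs[2L * i - 1L] <- s
    seqs[2L * i] <- alt
    offs[i] <- w$offset
  }
  if (inherits(model, "nldnn_baseline")) {
    X <- .encode_onehot(seqs)
    sc <- baseline_forward(model, X, "eval")$score
    d <- sc[seq(2, 2 * n, by = 2)] - sc[seq(1, 2 * n - 1, by = 2)]
    return(if (mode == "abs") abs(d) else d)
  }
  X <- .encode_onehot(seqs)
  pred <- matrix(0, window_len, 2L * n)
  at <- 1L
  while (at <= 2L * n) {
    idx <- at:min(2L * n, at + batch - 1L)
    pred[, idx] <- nldnn_predict(model, X[, , idx, drop = FALSE])
    at <- at + batch
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    D <- max(1L, offs[i] + 1L - D_radius):min(window_len, offs[i] + 1L + D_radius)
    d <- pred[D, 2L * i] - pred[D, 2L * i - 1L]
    out[i] <- if (mode == "abs") sum(abs(d)) else sum(d)
  }
  out
}

#' In-silico saturation mutagenesis
#'
#' Substitutes every position of a window by each non-reference base and
#' scores each substitution with the absolute-mode effect value, yielding a
#' 4 x L matrix whose reference-base entries are 0.
#'
#' @param model an "nldnn_model".
#' @param sequence window sequence of length L.
#' @param D_radius effect neighbourhood radius.
#' @param batch prediction batch size.
#' @return 4 x L matrix (rows A, C, G, T) of class "issm_matrix" with the
#'   reference sequence as attribute.
#' @export
issm <- function(model, sequence, D_radius = 100L, batch = 128L) {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  muts <- list()
  for (i in seq_len(L)) {
    for (b in setdiff(.onehot_rows, chars[i])) {
      alt <- sequence
      substr(alt, i, i) <- b
      muts[[length(muts) + 1L]] <- list(i = i, b = b, seq = alt)
    }
  }
  seqs <- c(sequence, vapply(muts, `[[`, character(1), "seq"))
  X <- .encode_onehot(seqs)
  nseq <- length(seqs)
  pred <- matrix(0, L, nseq)
  at <- 1L
  while (at <= nseq) {
    idx <- at:min(nseq, at + batch - 1L)
    pred[, idx] <- nldnn_predict(model, X[, , idx, drop = FALSE])
    at <- at + batch
  }
  M <- matrix(0, 4L, L, dimnames = list(.onehot_rows, NULL))
  for (m in seq_along(muts)) {
    i <- muts[[m]]$i
    D <- max(1L, i - D_radius):min(L, i + D_radius)
    M[muts[[m]]$b, i] <- sum(abs(pred[D, m + 1L] - pred[D, 1L]))
  }
  structure(M, class = c("issm_matrix", class(M)), reference = chars)
}

#' SNP classification metrics
#'
#' PR-AUC / ROC-AUC for separating positive (motif-disrupting) from
#' negative (LD-neighbour) variants by effect value.
#'
#' @param effects numeric effect values.
#' @param labels 0/1 labels.
#' @return list(prauc, rocauc).
#' @export
snp_classification <- function(effects, labels) {
  classification_metrics(effects, labels)
}

#' Causal-SNP prioritisation within an LD group
#'
#' The variant with the best (largest) effect value is called causal; the
#' hit indicator records whether that call matches the designated causal
#' variant (ties count as a miss), and the ratio is
#' effect(causal) / max(effect(others)) — above 1 exactly when the causal
#' variant is hit.
#'
#' @param effects effect values of the group's variants.
#' @param causal logical vector flagging the designated causal variant.
#' @return list(hit, ratio).
#' @export
prioritize_causal <- function(effects, causal) {
  stopifnot(length(effects) >= 2, sum(causal) == 1)
  ec <- effects[causal]
  eo <- max(effects[!causal])
  hit <- ec > eo                         # strict: ties are not a hit
  ratio <- if (eo == 0) {
    if (ec > 0) Inf else NaN
  } else ec / eo
  list(hit = hit, ratio = ratio)
}
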