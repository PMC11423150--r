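# Shared fixtures: tiny configs and small synthetic worlds, built in code.

tiny_model_config <- function(seed = 7L, dropout = 0) {
  model_config(conv_channels = c(3L, 4L, 5L), conv_kernels = c(5L, 3L, 3L),
               pool_sizes = c(2L, 2L, 2L), dropout = dropout, gru_hidden = 3L,
               sppm_scales = c(1L, 2L), disc_channels = c(3L, 3L, 3L),
               disc_hidden = 5L, seed = seed)
}

# a small world: 1-2 chromosomes of 20 kb, 8 peaks
small_spec <- function(seed = 5L, chroms = c("chr1", "chr2"), n_peaks = 8L,
                       noise_sd = 0.5, accessibility = FALSE) {
  synthetic_spec(genome_length_per_chrom = 20000L, chrom_names = chroms,
                 n_peaks = n_peaks, noise_sd = noise_sd,
                 accessibility = accessibility, seed = seed)
}

# brute-force average precision (descending unique thresholds)
ap_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  prev_rec <- 0
  auc <- 0
  for (t in ths) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / np
    auc <- auc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  auc
}

# all-pairs ROC-AUC oracle with tie credit 1/2
rocauc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# deterministic cached nucleotide-level model trained on a small world;
# heavy enough to carry signal, light enough for unit scope
.cache_env <- new.env(parent = emptyenv())

small_trained_model <- function() {
  if (!is.null(.cache_env$small_model)) return(.cache_env$small_model)
  spec <- small_spec(seed = 401L, n_peaks = 10L)
  ga <- make_genome(spec, "A")
  ds <- make_datasets(ga$genome, ga$truth, seed = 401L)
  tc <- desk_train_config(epochs = 18L, seed = 401L)
  tr <- train_nldnn(build_nldnn(desk_config(seed = 401L)),
                    ds$train, ds$val, tc)
  out <- list(model = tr$model, spec = spec, genome = ga$genome,
              truth = ga$truth, ds = ds)
  .cache_env$small_model <- out
  out
}

# a model whose output head is zeroed: constant-zero predictions
zero_output_model <- function(seed = 7L) {
  m <- build_nldnn(tiny_model_config(seed = seed))
  m$params$out_W[] <- 0
  m$params$out_b[] <- 0
  m
}
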