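# End-to-end experiment runner: one master seed fans out to named
# sub-seeds (data, model init, sampling, adaptation); every stage's
# configuration and metrics can be persisted as JSON for exact re-runs.

# named sub-seeds derived from one master seed (kept < 2^31)
fan_out_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000L
  list(data = base + 10L,
       model = base + 20L,
       train = base + 30L,
       adapt = base + 40L,
       variants = base + 50L)
}

#' Build labelled, encoded, split datasets for one species
#'
#' Runs the full preprocessing protocol: 600/100 window enumeration,
#' overlap labelling at 0.2, GC-matched negative selection, one-hot + log10
#' coverage encoding, and a chromosome split. With the default two-species
#' toy genomes the second chromosome is the test set; validation windows
#' are carved from the tail of the training chromosome with a one-window
#' buffer so that train and validation windows never overlap.
#'
#' @param genome genome assembly.
#' @param truth matching synthetic truth (or list with peaks + coverage).
#' @param window_len,offset window enumeration parameters.
#' @param min_overlap_ratio positive labelling threshold.
#' @param neg_per_pos GC-matched negatives per positive.
#' @param val_fraction fraction of the training chromosome reserved (from
#'   the tail) for validation.
#' @param test_chroms chromosomes held out as the test set.
#' @param seed sampling seed.
#' @return list(train, val, test) of window sets plus the label summary.
#' @export
make_datasets <- function(genome, truth, window_len = 600L, offset = 100L,
                          min_overlap_ratio = 0.2, neg_per_pos = 6L,
                          val_fraction = 0.15,
                          test_chroms = names(genome)[length(genome)],
                          seed = 1L) {
  win <- enumerate_windows(genome, window_len, offset)
  lab <- label_windows(win, truth$peaks, min_overlap_ratio)
  neg <- suppressWarnings(
    gc_match_negatives(lab$positives, lab$negative_pool,
                       n_select = neg_per_pos * nrow(lab$positives),
                       seed = seed))
  pos <- lab$positives
  pos$label <- "positive"
  neg$label <- "negative"
  allw <- rbind(pos, neg)
  ws <- encode_windows(allw, genome, truth$coverage,
                       accessibility = truth$accessibility)
  sp <- split_by_chromosome(ws, list(train = setdiff(names(genome), test_chroms),
                                     val = character(0), test = test_chroms))
  # carve validation from the training-chromosome tail with a buffer
  train_chroms <- unique(sp$train$meta$chrom)
  cut <- vapply(train_chroms, function(ch) {
    len <- nchar(genome[[ch]])
    floor(len * (1 - val_fraction))
  }, numeric(1))
  names(cut) <- train_chroms
  w_cut <- cut[sp$train$meta$chrom]
  is_val <- sp$train$meta$start >= w_cut
  is_buffer <- !is_val & (sp$train$meta$start > w_cut - window_len)
  list(train = subset_window_set(sp$train, !is_val & !is_buffer),
       val = subset_window_set(sp$train, is_val),
       test = sp$test,
       n_positive = nrow(pos), n_negative = nrow(neg))
}

#' Run a full experiment
#'
#' Modes: "within" trains and evaluates on species A; "cross" additionally
#' evaluates the species-A model on species B's test set; "cross_adapted"
#' follows with adversarial adaptation of the generator on species-B
#' training windows (evaluating the adapted model on species B);
#' "cross_transfer" instead fine-tunes with the species-classifier head.
#'
#' @param config list with elements: spec (a [synthetic_spec()]), mode,
#'   model (a [model_config()], seed overridden by the fan-out), train (a
#'   [train_config()]), adapt (an [adapt_config()], for the adapted modes),
#'   warmup (logical), out_dir (optional directory for JSON reports and
#'   checkpoints), seed (master seed).
#' @return list of reports (per stage) of class "nldnn_experiment".
#' @export
run_experiment <- function(config) {
  mode <- match.arg(config$mode,
                    c("within", "cross", "cross_adapted", "cross_transfer"))
  seeds <- fan_out_seeds(config$seed %||% 1L)
  spec <- config$spec %||% synthetic_spec()
  spec$seed <- seeds$data
  mcfg <- config$model %||% desk_config()
  mcfg$seed <- seeds$model
  tcfg <- config$train %||% desk_train_config()
  tcfg$seed <- seeds$train

  ga <- make_genome(spec, "A")
  dsa <- make_datasets(ga$genome, ga$truth, seed = seeds$train)

  if (isTRUE(config$warmup)) {
    wu <- warmup_select(mcfg, dsa$train, dsa$val, tcfg)
    model0 <- wu$model
  } else {
    model0 <- build_nldnn(mcfg)
  }
  tr <- train_nldnn(model0, dsa$train, dsa$val, tcfg)
  report <- list(mode = mode, seed = config$seed %||% 1L, seeds = seeds,
                 within = evaluate_model(tr$model, dsa$test))

  if (mode != "within") {
    gb <- make_genome(spec, "B")
    # a larger target validation split keeps the adaptation stopping metric
    # informative (the small default saturates at PR-AUC 1)
    dsb <- make_datasets(gb$genome, gb$truth, seed = seeds$train,
                         val_fraction = 0.3)
    report$cross <- evaluate_model(tr$model, dsb$test)
    if (mode %in% c("cross_adapted", "cross_transfer")) {
      acfg <- config$adapt %||% desk_adapt_config()
      acfg$seed <- seeds$adapt
      src_bind <- subset_window_set(
        dsa$train, dsa$train$meta$label == "positive")
      src_bind$meta$species_label <- 1L
      tgt_bind <- subset_window_set(
        dsb$train, dsb$train$meta$label == "positive")
      tgt_pool <- build_target_data(dsb$train, tgt_bind,
                                    p = acfg$binding_proportion,
                                    n_total = nrow(src_bind$meta),
                                    seed = acfg$seed)
      if (mode == "cross_adapted") {
        ad <- adapt(tr$model, src_bind, tgt_pool, target_val = dsb$val,
                    config = acfg)
        report$adapted <- evaluate_model(ad$model, dsb$test)
        report$adapt_history <- ad$history
        report$source_hash_ok <- ad$source_hash_ok
      } else {
        tl <- transfer_finetune(tr$model, src_bind, tgt_pool, config = acfg)
        report$transfer <- evaluate_model(tl$model, dsb$test)
        report$transfer_history <- tl$history
      }
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(tr$model, file.path(config$out_dir, "source_model.rds"))
    rep_json <- report
    rep_json$adapt_history <- NULL
    rep_json$transfer_history <- NULL
    jsonlite::write_json(rep_json,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "nldnn_experiment")
}
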