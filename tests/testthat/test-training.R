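# Loss oracles, the negative sampler, the learning-rate schedule, and the
# optimiser's ability to fit a small batch (capacity check).

test_that("the nucleotide-level loss matches a double-loop oracle", {
  expect_equal(nldnn_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(nldnn_loss(matrix(c(0, 0), 2, 1), matrix(c(2, 0), 2, 1)), 2)
  set.seed(1)
  for (rep in 1:20) {
    L <- sample(3:8, 1); N <- sample(2:5, 1)
    z <- matrix(stats::rnorm(L * N), L, N)
    zh <- matrix(stats::rnorm(L * N), L, N)
    loop <- 0
    for (i in seq_len(N)) for (j in seq_len(L)) loop <- loop + (z[j, i] - zh[j, i])^2
    expect_equal(nldnn_loss(z, zh), loop / (N * L), tolerance = 1e-6)
  }
  # L2 penalty on weights only
  m <- build_nldnn(tiny_model_config())
  wn <- nldnn:::weight_param_names(m$params)
  pen <- sum(vapply(m$params[wn], function(w) sum(w^2), numeric(1)))
  z <- matrix(0, 4, 2)
  expect_equal(nldnn_loss(z, z, m$params, alpha = 0.5), 0.5 * pen)
  expect_false(any(grepl("_b$|beta|gamma", wn)))
  # Poisson variant: minimum at exp(pred) = true
  zt <- matrix(c(2, 3), 2, 1)
  expect_lt(nldnn_loss(log(zt), zt, loss = "poisson"),
            nldnn_loss(log(zt) + 0.3, zt, loss = "poisson"))
})

test_that("the learning-rate schedule decays stepwise", {
  cfg <- train_config(seed = 1L)
  expect_equal(lr_schedule(25L, cfg), 0.001 * 0.9^2)
  expect_equal(lr_schedule(1L, cfg), 0.001)
  for (e in 1:40) {
    expect_equal(lr_schedule(e, cfg), cfg$lr0 * cfg$lr_decay^((e - 1) %/% 10))
  }
})

test_that("epoch batches use all positives plus 3x negatives without replacement", {
  cfg <- train_config(batch_size = 16L, neg_ratio = 3L, seed = 5L)
  pos_idx <- 1:10
  neg_idx <- 11:130        # pool of 120
  sampler <- negative_sampler(length(neg_idx), seed = cfg$seed)
  eb1 <- epoch_batches(pos_idx, sampler, neg_idx, cfg, 1L)
  all1 <- unlist(eb1$batches)
  expect_length(all1, 40L)
  expect_equal(sort(intersect(all1, pos_idx)), pos_idx)
  expect_length(setdiff(all1, pos_idx), 30L)

  # union over ceiling(120 / 30) epochs covers the whole pool exactly once
  sampler <- negative_sampler(length(neg_idx), seed = cfg$seed)
  seen <- integer(0)
  for (e in 1:4) {
    eb <- epoch_batches(pos_idx, sampler, neg_idx, cfg, e)
    sampler <- eb$sampler
    seen <- c(seen, setdiff(unlist(eb$batches), pos_idx))
  }
  expect_equal(sort(unique(seen)), neg_idx)
  expect_length(seen, 120L)              # no reuse before exhaustion

  # determinism
  s1 <- negative_sampler(120L, seed = cfg$seed)
  s2 <- negative_sampler(120L, seed = cfg$seed)
  e1 <- epoch_batches(pos_idx, s1, neg_idx, cfg, 3L)
  e2 <- epoch_batches(pos_idx, s2, neg_idx, cfg, 3L)
  expect_identical(e1$batches, e2$batches)

  # pool smaller than the epoch demand: reshuffle mid-epoch with a warning
  s3 <- negative_sampler(5L, seed = 1L)
  expect_warning(dr <- sampler_draw(s3, 12L), "reshuffling")
  expect_length(dr$idx, 12L)
})

test_that("the network can fit a small batch (capacity check)", {
  spec <- small_spec(seed = 71L, chroms = "chr1", n_peaks = 6L)
  ga <- make_genome(spec, "A")
  win <- enumerate_windows(ga$genome)
  lab <- label_windows(win, ga$truth$peaks, 0.2)
  lab$positives$label <- "positive"
  neg <- lab$negative_pool[1:4, ]
  neg$label <- "negative"
  ws <- encode_windows(rbind(lab$positives[1:4, ], neg), ga$genome,
                       ga$truth$coverage)
  m <- build_nldnn(desk_config(seed = 6L))
  opt <- nldnn:::adam_init(m$params)
  l0 <- NA
  l <- NA
  for (s in 1:200) {
    fw <- nldnn_forward(m, ws$X, "train")
    m$bn_state <- fw$bn_state
    l <- mean((fw$pred - ws$target)^2)
    if (s == 1) l0 <- l
    if (l < 0.1 * l0) break      # property reached within the step budget
    bw <- nldnn_backward(m, fw, 2 * (fw$pred - ws$target) / length(ws$target))
    st <- nldnn:::adam_step(m$params, bw$grads, opt, 1e-3)
    m$params <- st$params
    opt <- st$state
  }
  expect_lt(l, 0.1 * l0)
})

test_that("training histories and warm-up selection follow their contracts", {
  spec <- small_spec(seed = 81L, chroms = "chr1", n_peaks = 6L)
  ga <- make_genome(spec, "A")
  ds <- make_datasets(ga$genome, ga$truth, test_chroms = character(0),
                      seed = 81L)
  tc <- desk_train_config(epochs = 2L, seed = 81L)
  mc <- tiny_model_config(seed = 30L)
  tr <- train_nldnn(build_nldnn(mc), ds$train, ds$val, tc)
  expect_equal(nrow(tr$history), 2L)
  expect_true(all(is.finite(tr$history$train_loss)))

  wcfg <- tc
  wcfg$warmup_inits <- 2L
  wcfg$warmup_epochs <- 1L
  wu <- warmup_select(mc, ds$train, ds$val, wcfg)
  expect_equal(wu$val_prauc, max(wu$scores))
  expect_true(wu$chosen %in% wu$seeds)
})
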