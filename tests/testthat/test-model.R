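# Architecture contracts: shapes, determinism, the generator/predictor
# partition, gradient flow, and finite-difference correctness of the
# hand-written backward passes.

test_that("builds are deterministic and the output head is linear", {
  cfg <- tiny_model_config(seed = 7L)
  m1 <- build_nldnn(cfg)
  m2 <- build_nldnn(cfg)
  expect_identical(m1$params, m2$params)

  mz <- zero_output_model()
  X <- array(stats::rnorm(4 * 40 * 2), c(4, 40, 2))
  expect_true(all(nldnn_forward(mz, X, "eval")$pred == 0))
})

test_that("output length equals input length and padding handles remainders", {
  m <- build_nldnn(tiny_model_config())    # pool product 8
  for (L in c(40L, 80L, 120L)) {
    X <- array(stats::rnorm(4 * L * 2), c(4, L, 2))
    expect_equal(dim(nldnn_forward(m, X, "eval")$pred), c(L, 2L))
  }
  # arbitrary length via right-padding
  X <- array(stats::rnorm(4 * 43 * 1), c(4, 43, 1))
  expect_equal(nrow(nldnn_predict(m, X)), 43L)
  expect_error(nldnn_forward(m, X, "eval"), "divisible")
})

test_that("eval mode is deterministic and batch-order equivariant", {
  m <- build_nldnn(tiny_model_config(seed = 3L, dropout = 0.3))
  X <- array(stats::rnorm(4 * 40 * 3), c(4, 40, 3))
  p1 <- nldnn_forward(m, X, "eval")$pred
  p2 <- nldnn_forward(m, X, "eval")$pred
  expect_identical(p1, p2)
  # identical windows -> identical columns
  Xr <- X[, , c(1, 1, 2), drop = FALSE]
  pr <- nldnn_forward(m, Xr, "eval")$pred
  expect_equal(pr[, 1], pr[, 2])
  # permuting the batch permutes the outputs
  perm <- c(3, 1, 2)
  pp <- nldnn_forward(m, X[, , perm, drop = FALSE], "eval")$pred
  expect_equal(pp, p1[, perm])
})

test_that("generator/predictor partition is exact and composition is identity", {
  m <- build_nldnn(tiny_model_config(seed = 9L))
  sp <- split_generator_predictor(m)
  expect_length(intersect(names(sp$generator$params),
                          names(sp$predictor$params)), 0)
  expect_equal(sum(lengths(sp$generator$params)) +
                 sum(lengths(sp$predictor$params)),
               sum(lengths(m$params)))
  X <- array(stats::rnorm(4 * 40 * 2), c(4, 40, 2))
  gf <- generator_forward(sp$generator$params, m$config, X, "eval")
  expect_length(gf$skips, 3L)          # three skips + the bottleneck
  pf <- predictor_forward(sp$predictor$params, sp$predictor$bn_state,
                          m$config, gf, "eval")
  expect_identical(pf$pred, nldnn_forward(m, X, "eval")$pred)
})

test_that("every parameter receives gradient on a random batch", {
  m <- build_nldnn(tiny_model_config(seed = 2L))
  set.seed(4)
  X <- array(stats::rnorm(4 * 40 * 3), c(4, 40, 3))
  tgt <- matrix(abs(stats::rnorm(40 * 3)), 40, 3)
  fw <- nldnn_forward(m, X, "train")
  bw <- nldnn_backward(m, fw, 2 * (fw$pred - tgt) / length(tgt))
  dead <- names(Filter(function(nm) all(bw$grads[[nm]] == 0),
                       setNames(names(m$params), names(m$params))))
  expect_length(dead, 0)
})

test_that("analytic gradients match finite differences through the full model", {
  m <- build_nldnn(tiny_model_config(seed = 5L))
  set.seed(6)
  X <- array(stats::rnorm(4 * 24 * 2), c(4, 24, 2))
  tgt <- matrix(stats::rnorm(24 * 2), 24, 2)
  loss_of <- function(params) {
    m2 <- m
    m2$params <- params
    mean((nldnn_forward(m2, X, "train")$pred - tgt)^2)
  }
  fw <- nldnn_forward(m, X, "train")
  bw <- nldnn_backward(m, fw, 2 * (fw$pred - tgt) / length(tgt), want_dx = TRUE)
  eps <- 1e-5
  for (nm in c("enc1_W", "gruf_Uh", "grur_Wz", "sppm1_W", "rrb2_a_W",
               "rrb3_bn_gamma", "up1_W", "up3_bn_beta", "out_W", "gproj_W")) {
    i <- sample(length(m$params[[nm]]), 1)
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    ng <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], ng, tolerance = 1e-3,
                 label = paste("grad", nm))
  }
  # input gradient (used by attribution)
  i <- sample(length(X), 1)
  xp <- X; xp[i] <- xp[i] + eps
  xm <- X; xm[i] <- xm[i] - eps
  m2 <- m
  ng <- (mean((nldnn_forward(m2, xp, "train")$pred - tgt)^2) -
           mean((nldnn_forward(m2, xm, "train")$pred - tgt)^2)) / (2 * eps)
  expect_equal(bw$dx[i], ng, tolerance = 1e-3)
})

test_that("discriminator and baseline meet their output contracts", {
  cfg <- tiny_model_config(seed = 8L)
  m <- build_nldnn(cfg)
  X <- array(stats::rnorm(4 * 40 * 3), c(4, 40, 3))
  gf <- generator_forward(m$params, cfg, X, "eval")
  D <- build_discriminator(cfg, bottleneck_len = dim(gf$bottleneck)[2], seed = 1L)
  p <- disc_forward(D, gf$bottleneck, "eval")$prob
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, disc_forward(D, gf$bottleneck, "eval")$prob)

  bl <- build_baseline(cfg, channels = c(4L, 5L), kernels = c(5L, 3L), seed = 2L)
  sc <- baseline_forward(bl, X, "eval")$score
  expect_length(sc, 3L)
  expect_true(all(is.finite(sc)))
})

test_that("checkpoints round-trip the full model state", {
  m <- build_nldnn(tiny_model_config(seed = 10L))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  X <- array(stats::rnorm(4 * 40 * 1), c(4, 40, 1))
  expect_identical(nldnn_forward(m2, X, "eval")$pred,
                   nldnn_forward(m, X, "eval")$pred)
  tab <- capture.output(describe_model(m))
  expect_true(any(grepl("generator", tab)))
  expect_true(any(grepl("total parameters", tab)))
})
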