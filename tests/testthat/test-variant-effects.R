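# Variant-effect scores, saturation mutagenesis and causal prioritisation.

test_that("effect scores vanish in degenerate cases and match a loop oracle", {
  mz <- zero_output_model()                    # constant (zero) output
  spec <- small_spec(seed = 101L, chroms = "chr1")
  g <- make_genome(spec, "A")
  vt <- make_variant_set(g$truth, g$genome, n_pos = 2L, n_neg_per_pos = 1L,
                         seed = 5L)
  expect_equal(effect_scores(mz, g$genome, vt, window_len = 80L,
                             D_radius = 20L), rep(0, nrow(vt)))

  # alt == ref is identically zero
  v_same <- vt[1, ]
  v_same$alt <- v_same$ref
  m <- build_nldnn(tiny_model_config(seed = 3L))
  expect_equal(effect_scores(m, g$genome, v_same, window_len = 80L,
                             D_radius = 20L), 0)

  # ref mismatch is a named error
  v_bad <- vt[1, ]
  v_bad$ref <- setdiff(c("A", "C", "G", "T"), v_bad$ref)[1]
  expect_error(effect_scores(m, g$genome, v_bad, window_len = 80L), "mismatch")

  # per-base loop oracle over the neighbourhood, abs and signed modes
  for (md in c("abs", "signed")) {
    es <- effect_scores(m, g$genome, vt, window_len = 80L, D_radius = 15L,
                        mode = md)
    for (i in seq_len(nrow(vt))) {
      w <- nldnn:::.window_for_variant(g$genome, vt$chrom[i], vt$pos[i], 80L)
      s <- substr(g$genome[[vt$chrom[i]]], w$start + 1L, w$start + 80L)
      alt <- s
      substr(alt, w$offset + 1L, w$offset + 1L) <- vt$alt[i]
      pr <- nldnn_predict(m, encode_window(s)$onehot)
      pa <- nldnn_predict(m, encode_window(alt)$onehot)
      D <- max(1L, w$offset + 1L - 15L):min(80L, w$offset + 1L + 15L)
      manual <- 0
      for (j in D) {
        d <- pa[j, 1] - pr[j, 1]
        manual <- manual + if (md == "abs") abs(d) else d
      }
      expect_equal(es[i], manual, tolerance = 1e-10)
    }
  }

  # abs mode is symmetric under swapping ref and alt (positive variants sit
  # in well-separated peaks, so their windows are independent)
  vtp <- vt[vt$label == 1L, ]
  vswap <- vtp
  gmut <- g$genome
  for (i in seq_len(nrow(vtp))) {
    substr(gmut[[vtp$chrom[i]]], vtp$pos[i] + 1L, vtp$pos[i] + 1L) <- vtp$alt[i]
    vswap$ref[i] <- vtp$alt[i]
    vswap$alt[i] <- vtp$ref[i]
  }
  es_fwd <- effect_scores(m, gmut, vswap, window_len = 80L, D_radius = 15L)
  es_orig <- effect_scores(m, g$genome, vtp, window_len = 80L, D_radius = 15L)
  expect_equal(es_fwd, es_orig, tolerance = 1e-10)
})

test_that("saturation mutagenesis fills 3 of 4 entries per column", {
  spec <- small_spec(seed = 103L, chroms = "chr1")
  g <- make_genome(spec, "A")
  s <- substr(g$genome$chr1, 1, 48)
  mz <- zero_output_model()
  M0 <- issm(mz, s, D_radius = 10L)
  expect_equal(dim(M0), c(4L, 48L))
  expect_true(all(M0 == 0))

  m <- build_nldnn(tiny_model_config(seed = 4L))
  M <- issm(m, s, D_radius = 10L)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(48)) {
    expect_equal(unname(M[chars[i], i]), 0)         # reference entries zero
  }
  expect_true(all(colSums(M != 0) == 3L))
  # entries match one-at-a-time effect scores
  for (i in c(5L, 24L, 40L)) {
    b <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
    alt <- s
    substr(alt, i, i) <- b
    pr <- nldnn_predict(m, encode_window(s)$onehot)
    pa <- nldnn_predict(m, encode_window(alt)$onehot)
    D <- max(1L, i - 10L):min(48L, i + 10L)
    expect_equal(unname(M[b, i]), sum(abs(pa[D, 1] - pr[D, 1])),
                 tolerance = 1e-10)
  }
})

test_that("SNP classification and causal prioritisation behave as specified", {
  expect_equal(snp_classification(c(3, 2, 1, 0), c(1, 1, 0, 0))$rocauc, 1)
  set.seed(11)
  eff <- stats::rnorm(2000)
  lab <- sample(rep(0:1, 1000))
  expect_lt(abs(snp_classification(eff, lab)$rocauc - 0.5), 0.04)

  pc <- prioritize_causal(c(2, 1, 0.5), c(TRUE, FALSE, FALSE))
  expect_true(pc$hit)
  expect_equal(pc$ratio, 2)
  pc2 <- prioritize_causal(c(0.5, 1, 0.2), c(TRUE, FALSE, FALSE))
  expect_false(pc2$hit)
  expect_equal(pc2$ratio, 0.5)
  # ties are not hits; zero denominator flags infinity
  expect_false(prioritize_causal(c(1, 1), c(TRUE, FALSE))$hit)
  expect_equal(prioritize_causal(c(1, 0), c(TRUE, FALSE))$ratio, Inf)
  # consistency: hit <=> ratio > 1 on random groups
  set.seed(12)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    e <- stats::runif(k)
    cz <- rep(FALSE, k)
    cz[sample(k, 1)] <- TRUE
    r <- prioritize_causal(e, cz)
    expect_equal(r$hit, r$ratio > 1)
  }
})
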