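# Chromosome scanning, top-fraction selection, peak intersection and the
# exact-p-value PWM scan.

test_that("scanning tiles the chromosome and records leftmost maxima", {
  g <- structure(list(chrX = strrep("ACGT", 450)), class = "genome_assembly")
  mz <- build_nldnn(desk_config(seed = 2L))
  mz$params$out_W[] <- 0
  mz$params$out_b[] <- 0
  sc <- scan_chromosome(mz, g, "chrX")               # 1800 bp -> 3 windows
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$start, c(0L, 600L, 1200L))
  expect_true(all(sc$max_value == 0))
  expect_equal(sc$max_pos, sc$start)                 # leftmost ties

  m <- build_nldnn(desk_config(seed = 3L))
  sc2 <- scan_chromosome(m, g, "chrX")
  # per-window loop oracle
  for (i in 1:3) {
    s <- substr(g$chrX, sc2$start[i] + 1L, sc2$start[i] + 600L)
    pr <- nldnn_predict(m, encode_window(s)$onehot)
    expect_equal(sc2$max_value[i], max(pr), tolerance = 1e-12)
    expect_equal(sc2$max_pos[i], sc2$start[i] + which.max(pr) - 1L)
    expect_true(sc2$max_pos[i] >= sc2$start[i] && sc2$max_pos[i] < sc2$end[i])
  }
})

test_that("top-region selection is a sorted prefix, monotone in the fraction", {
  scan <- data.frame(chrom = "c", start = seq(0L, 299L * 600L, by = 600L))
  scan$end <- scan$start + 600L
  set.seed(5)
  scan$max_value <- stats::runif(300)
  expect_equal(nrow(select_top_regions(scan, 0.01)), 3L)
  expect_equal(nrow(select_top_regions(scan, 1.0)), 300L)
  top <- select_top_regions(scan, 0.05)
  o <- order(-scan$max_value, scan$start)
  expect_equal(top$start, scan$start[o[1:15]])
  sizes <- vapply(c(0.01, 0.05, 0.2, 0.6, 1), function(f) {
    nrow(select_top_regions(scan, f))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # ties at the cutoff resolved by leftmost start
  scan2 <- scan
  scan2$max_value <- rep(1, 300)
  expect_equal(select_top_regions(scan2, 0.01)$start, scan2$start[1:3])
})

test_that("intersection ratio counts any >=1-base overlap", {
  regions <- data.frame(chrom = "c", start = c(0L, 1000L, 2000L),
                        end = c(600L, 1600L, 2600L))
  expect_equal(intersect_ratio(regions, data.frame(chrom = "c", start = 0L,
                                                   end = 3000L)), 1)
  expect_equal(intersect_ratio(regions, regions[0, ]), 0)
  peaks <- data.frame(chrom = "c", start = c(599L, 1600L), end = c(700L, 1700L))
  # region 1 overlaps by one base; region 2 abuts (no overlap); region 3 none
  expect_equal(intersect_ratio(regions, peaks), 1 / 3)
  # all-pairs oracle on random sets
  set.seed(6)
  for (rep in 1:10) {
    rg <- data.frame(chrom = "c", start = sample(0:5000, 8))
    rg$end <- rg$start + 300L
    pk <- data.frame(chrom = "c", start = sample(0:5000, 5))
    pk$end <- pk$start + sample(50:400, 5)
    manual <- mean(vapply(seq_len(8), function(i) {
      any(pmax(rg$start[i], pk$start) < pmin(rg$end[i], pk$end))
    }, logical(1)))
    expect_equal(intersect_ratio(rg, pk), manual)
  }
})

test_that("exact PWM p-values match brute-force enumeration on a short motif", {
  set.seed(7)
  pwm <- matrix(stats::rgamma(4 * 5, 1), 4, 5,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  bg <- rep(0.25, 4)
  thr <- pwm_score_threshold(pwm, bg, alpha = 0.01)
  # enumerate all 4^5 sequences under the background
  lo <- thr$lo
  combos <- as.matrix(expand.grid(rep(list(1:4), 5)))
  scores <- vapply(seq_len(nrow(combos)), function(r) {
    sum(lo[cbind(combos[r, ], 1:5)])
  }, numeric(1))
  probs <- rep(0.25^5, length(scores))
  expect_equal(thr$achieved_alpha, sum(probs[scores >= thr$threshold]),
               tolerance = 1e-9)
  expect_lt(thr$achieved_alpha, 0.01)
  # no stricter achievable threshold sits below alpha
  below <- max(scores[scores < thr$threshold])
  expect_gte(sum(probs[scores >= below]), 0.01)
})

test_that("hit calls equal a brute-force scan on a toy region", {
  spec <- small_spec(seed = 111L, chroms = "chr1")
  g <- make_genome(spec, "A")
  s <- substr(g$genome$chr1, 1, 1000)
  pwm <- spec$motif_pwm
  thr <- pwm_score_threshold(pwm, alpha = 1e-4)
  hits <- pwm_count_hits(s, thr)
  # brute force: score every position on both strands from the sequence
  chars <- strsplit(s, "")[[1]]
  lo <- thr$lo
  W <- ncol(lo)
  rcmap <- c(A = "T", C = "G", G = "C", T = "A")
  manual <- 0
  for (i in 1:(1000 - W + 1)) {
    sub <- chars[i:(i + W - 1)]
    fs <- sum(lo[cbind(match(sub, c("A", "C", "G", "T")), 1:W)])
    rc <- rev(rcmap[sub])
    rs <- sum(lo[cbind(match(rc, c("A", "C", "G", "T")), 1:W)])
    manual <- manual + (fs >= thr$threshold) + (rs >= thr$threshold)
  }
  expect_equal(hits, manual)

  # a region containing the exact consensus is always a hit
  cons <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  region <- paste0(strrep("A", 40), cons, strrep("T", 40))
  expect_gt(pwm_count_hits(region, thr), 0)
  gg <- structure(list(r1 = region), class = "genome_assembly")
  expect_equal(motif_instance_ratio(data.frame(chrom = "r1", start = 0L,
                                               end = nchar(region)),
                                    gg, pwm), 1)
})

test_that("degenerate PWM columns get a pseudocount", {
  pwm <- matrix(c(1, 0, 0, 0), 4, 3,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_message(thr <- pwm_score_threshold(pwm, alpha = 0.05), "pseudocount")
  expect_true(is.finite(thr$threshold))
})
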