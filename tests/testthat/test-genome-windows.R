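# Window enumeration, overlap labelling, GC matching, encoding and splits,
# each against a brute-force oracle where one exists.

test_that("window enumeration matches the analytic count and an overlap oracle", {
  g <- structure(list(chr1 = paste(rep("ACGT", 250), collapse = "")),
                 class = "genome_assembly")   # 1000 bp
  w <- enumerate_windows(g, 600L, 100L)
  expect_equal(w$start, seq(0L, 400L, by = 100L))
  expect_equal(nrow(w), floor((1000 - 600) / 100) + 1)

  expect_equal(nrow(enumerate_windows(g, 600L, 100L,
                                      exclude = data.frame(chrom = "chr1",
                                                           start = 0L,
                                                           end = 1000L))), 0L)
  # random exclusions vs brute force over every start
  set.seed(8)
  for (rep in 1:5) {
    st <- sort(sample(0:900, 3))
    ex <- data.frame(chrom = "chr1", start = st, end = st + sample(20:150, 3))
    w2 <- enumerate_windows(g, 600L, 100L, exclude = ex)
    keep <- vapply(seq(0L, 400L, by = 100L), function(s) {
      !any(pmax(s, ex$start) < pmin(s + 600L, ex$end))
    }, logical(1))
    expect_equal(w2$start, seq(0L, 400L, by = 100L)[keep])
  }
  # a chromosome shorter than the window yields nothing
  gshort <- structure(list(chrA = strrep("A", 100L)), class = "genome_assembly")
  expect_message(ws <- enumerate_windows(gshort, 600L, 100L), "shorter")
  expect_equal(nrow(ws), 0L)
})

test_that("overlap labelling applies the strict 0.2 rule with a gray zone", {
  w <- data.frame(chrom = "chr1", start = 0L, end = 600L, gc = 0.5)
  lab <- label_windows(w, data.frame(chrom = "chr1", start = 0L, end = 121L), 0.2)
  expect_equal(nrow(lab$positives), 1L)   # 121/600 > 0.2
  lab2 <- label_windows(w, data.frame(chrom = "chr1", start = 590L, end = 700L), 0.2)
  expect_equal(nrow(lab2$positives), 0L)  # overlap 10: neither set
  expect_equal(nrow(lab2$negative_pool), 0L)
  lab3 <- label_windows(w, data.frame(chrom = "chr1", start = 900L, end = 950L), 0.2)
  expect_equal(nrow(lab3$negative_pool), 1L)

  # per-base counting oracle on random peak sets
  set.seed(13)
  g <- small_spec(seed = 61L, chroms = "chr1")
  ga <- make_genome(g, "A")
  wins <- enumerate_windows(ga$genome, 600L, 100L)
  st <- sort(sample(0:19000, 12))
  peaks <- data.frame(chrom = "chr1", start = st, end = st + sample(50:700, 12))
  lab4 <- label_windows(wins, peaks, 0.2)
  base_cov <- rep(FALSE, 20000L)
  for (i in seq_len(nrow(peaks))) {
    base_cov[(peaks$start[i] + 1L):min(20000L, peaks$end[i])] <- TRUE
  }
  for (i in seq_len(nrow(wins))) {
    ov <- sum(base_cov[(wins$start[i] + 1L):wins$end[i]])
    in_pos <- any(lab4$positives$start == wins$start[i])
    in_neg <- any(lab4$negative_pool$start == wins$start[i])
    expect_equal(in_pos, ov / 600 > 0.2)
    expect_equal(in_neg, ov == 0)
  }
})

test_that("GC matching reproduces the positive GC distribution", {
  pos <- data.frame(chrom = "c", start = 1:30, end = 2:31, gc = 0.5)
  pool <- data.frame(chrom = "c", start = 1:200, end = 2:201,
                     gc = rep(c(0.1, 0.5), each = 100))
  sel <- gc_match_negatives(pos, pool, n_select = 60L, bins = 10L, seed = 2L)
  expect_equal(nrow(sel), 60L)
  expect_true(all(sel$gc == 0.5))

  expect_equal(nrow(gc_match_negatives(pos, pool, n_select = 0L)), 0L)
  expect_warning(all_of <- gc_match_negatives(pos, pool, n_select = 1000L),
                 "smaller")
  expect_equal(nrow(all_of), 200L)
  expect_error(gc_match_negatives(pos, pool[0, ]), "empty")

  # KS distance improves over the raw pool on a skewed pool
  set.seed(3)
  pos2 <- data.frame(chrom = "c", start = 1:150, end = 2:151,
                     gc = rbeta(150, 8, 4))
  pool2 <- data.frame(chrom = "c", start = 1:2000, end = 2:2001,
                      gc = rbeta(2000, 2, 8))
  sel2 <- suppressWarnings(gc_match_negatives(pos2, pool2, n_select = 300L,
                                              seed = 4L))
  ks_matched <- suppressWarnings(ks.test(sel2$gc, pos2$gc)$statistic)
  ks_raw <- suppressWarnings(ks.test(pool2$gc, pos2$gc)$statistic)
  expect_lt(ks_matched, ks_raw)
})

test_that("one-hot encoding is exact, invertible and log-scales coverage", {
  enc <- encode_window("ACGT")
  expect_equal(enc$onehot, diag(4), ignore_attr = TRUE)
  expect_equal(encode_window("ACGT", coverage = rep(0, 4))$target, rep(0, 4))
  expect_equal(encode_window("ACGT", coverage = c(9, 99, 0, 1))$target,
               log10(1 + c(9, 99, 0, 1)))
  encN <- encode_window("ANGT")
  expect_equal(colSums(encN$onehot), c(1, 0, 1, 1))
  expect_error(encode_window("ACXT"), "position 3")

  # invertibility for ACGT sequences
  s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  oh <- encode_window(s)$onehot
  rec <- paste(c("A", "C", "G", "T")[apply(oh, 2, which.max)], collapse = "")
  expect_identical(rec, s)

  # accessibility becomes a fifth input row
  enc5 <- encode_window("ACGT", accessibility = c(1, 2, 3, 4))
  expect_equal(dim(enc5$onehot), c(5L, 4L))
  expect_equal(enc5$onehot[5, ], c(1, 2, 3, 4))
})

test_that("chromosome splits conserve windows and reject overlaps", {
  w <- data.frame(chrom = rep(c("chr1", "chr2", "chr3"), each = 4),
                  start = rep(0:3 * 100L, 3), end = rep(0:3 * 100L + 600L, 3),
                  gc = 0.5)
  sp <- split_by_chromosome(w, list(train = "chr1", val = "chr2", test = "chr3"))
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(w))
  expect_equal(unique(sp$test$chrom), "chr3")
  # unlisted chromosomes go to train
  sp2 <- split_by_chromosome(w, list(test = "chr3"))
  expect_equal(nrow(sp2$train), 8L)
  # all windows on one chromosome listed as test
  w1 <- w[w$chrom == "chr1", ]
  sp3 <- split_by_chromosome(w1, list(test = "chr1"))
  expect_equal(nrow(sp3$train), 0L)
  expect_equal(nrow(sp3$test), 4L)
  expect_error(split_by_chromosome(w, list(train = "chr1", val = "chr1")),
               "overlap")
  # direct membership oracle
  for (i in seq_len(nrow(w))) {
    grp <- c(chr1 = "train", chr2 = "val", chr3 = "test")[w$chrom[i]]
    expect_true(w$start[i] %in% sp[[grp]]$start[sp[[grp]]$chrom == w$chrom[i]])
  }
})

test_that("windows written to BED re-read with exact coordinates", {
  w <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 1234L),
                  end = c(600L, 1834L))
  f <- tempfile(fileext = ".bed")
  write_bed(w, f)
  w2 <- read_bed(f)
  expect_equal(w2$start, w$start)
  expect_equal(w2$end, w$end)
  expect_equal(w2$chrom, w$chrom)
})
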