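# Synthetic two-species generator: determinism, construction contracts,
# species-shift and variant-set properties.

test_that("generation is deterministic and species-specific under one spec", {
  spec <- small_spec(seed = 11L)
  a1 <- make_genome(spec, "A")
  a2 <- make_genome(spec, "A")
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$truth$coverage, a2$truth$coverage)
  expect_identical(a1$truth$peaks, a2$truth$peaks)
  b <- make_genome(spec, "B")
  expect_false(identical(a1$genome$chr1, b$genome$chr1))
  # FASTA byte-identity
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(a1$genome, f1)
  write_genome_fasta(a2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("no-signal and noiseless constructions behave analytically", {
  spec0 <- small_spec(seed = 3L, chroms = "chr1", n_peaks = 0L)
  g0 <- make_genome(spec0, "A")
  expect_equal(nrow(g0$truth$peaks), 0L)
  expect_true(all(g0$truth$coverage$chr1 >= 0))
  # pure noise: truncated normal, mean well below the peak amplitude range
  expect_lt(mean(g0$truth$coverage$chr1), 1)

  spec1 <- synthetic_spec(genome_length_per_chrom = 20000L,
                          chrom_names = "chr1", n_peaks = 1L,
                          max_motifs_per_peak = 1L, noise_sd = 0,
                          seed = 9L)
  g1 <- make_genome(spec1, "A")
  amp <- g1$truth$peaks$score[1]
  expect_equal(max(g1$truth$coverage$chr1), amp, tolerance = 1e-12)
  summit <- which.max(g1$truth$coverage$chr1) - 1L
  expect_gte(summit, g1$truth$peaks$start[1])
  expect_lt(summit, g1$truth$peaks$end[1])
})

test_that("every motif instance lies inside exactly one peak", {
  spec <- small_spec(seed = 21L)
  g <- make_genome(spec, "B")
  mp <- g$truth$motif_positions
  pk <- g$truth$peaks
  for (i in seq_len(nrow(mp))) {
    inside <- sum(pk$chrom == mp$chrom[i] & pk$start <= mp$start[i] &
                    pk$end >= mp$end[i])
    expect_equal(inside, 1L)
  }
  # planted instances are present in the sequence (consensus-dominated PWM)
  W <- ncol(spec$motif_pwm)
  hits <- vapply(seq_len(nrow(mp)), function(i) {
    s <- substr(g$genome[[mp$chrom[i]]], mp$start[i] + 1L, mp$end[i])
    cons <- paste(rownames(spec$motif_pwm)[apply(spec$motif_pwm, 2, which.max)],
                  collapse = "")
    if (mp$strand[i] == "-") s <- nldnn:::.revcomp(s)
    sum(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]])
  }, numeric(1))
  expect_gt(mean(hits / W), 0.9)   # mostly consensus bases
})

test_that("species differ in 3-mer composition more than replicate draws", {
  # chi-square statistic between 3-mer count vectors, median over seeds
  chi2 <- function(c1, c2) {
    e <- (c1 + c2) / 2
    keep <- e > 0
    sum((c1[keep] - e[keep])^2 / e[keep]) + sum((c2[keep] - e[keep])^2 / e[keep])
  }
  kmer3 <- function(seq) {
    Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 3)
  }
  cross <- numeric(0)
  within <- numeric(0)
  for (sd in 1:6) {
    spec1 <- small_spec(seed = 600L + sd, chroms = "chr1", n_peaks = 4L)
    spec2 <- small_spec(seed = 700L + sd, chroms = "chr1", n_peaks = 4L)
    a1 <- kmer3(make_genome(spec1, "A")$genome$chr1)
    a2 <- kmer3(make_genome(spec2, "A")$genome$chr1)
    b1 <- kmer3(make_genome(spec1, "B")$genome$chr1)
    within <- c(within, chi2(a1, a2))
    cross <- c(cross, chi2(a1, b1))
  }
  expect_gt(median(cross), median(within))
})

test_that("coverage maxima in peaks clear the background when signal >> noise", {
  spec <- small_spec(seed = 31L, chroms = "chr1", n_peaks = 6L, noise_sd = 0.5)
  # amplitude_min = 7 > 4 * noise_sd = 2
  g <- make_genome(spec, "A")
  cov <- g$truth$coverage$chr1
  inpeak <- rep(FALSE, length(cov))
  for (i in seq_len(nrow(g$truth$peaks))) {
    inpeak[(g$truth$peaks$start[i] + 1L):g$truth$peaks$end[i]] <- TRUE
  }
  peak_maxima <- vapply(seq_len(nrow(g$truth$peaks)), function(i) {
    max(cov[(g$truth$peaks$start[i] + 1L):g$truth$peaks$end[i]])
  }, numeric(1))
  expect_true(all(peak_maxima > quantile(cov[!inpeak], 0.99)))
})

test_that("variant sets respect count, reference and LD-distance contracts", {
  spec <- small_spec(seed = 41L)
  g <- make_genome(spec, "A")
  vt <- make_variant_set(g$truth, g$genome, n_pos = 1L, n_neg_per_pos = 3L,
                         ld_radius = 300L, seed = 2L)
  expect_equal(sum(vt$label == 1L), 1L)
  expect_lte(sum(vt$label == 0L), 3L)

  vt2 <- make_variant_set(g$truth, g$genome, n_pos = 5L, n_neg_per_pos = 4L,
                          ld_radius = 400L, seed = 3L)
  # every ref base matches the genome
  for (i in seq_len(nrow(vt2))) {
    expect_identical(substr(g$genome[[vt2$chrom[i]]], vt2$pos[i] + 1L,
                            vt2$pos[i] + 1L), vt2$ref[i])
    expect_false(vt2$ref[i] == vt2$alt[i])
  }
  # exhaustive-scan oracle: negative distance to nearest positive <= radius,
  # and negatives fall outside every motif interval
  posrows <- vt2[vt2$label == 1L, ]
  mp <- g$truth$motif_positions
  for (i in which(vt2$label == 0L)) {
    dists <- abs(vt2$pos[i] - posrows$pos[posrows$chrom == vt2$chrom[i]])
    expect_lte(min(dists), 400L)
    inmotif <- any(mp$chrom == vt2$chrom[i] & mp$start <= vt2$pos[i] &
                     mp$end > vt2$pos[i])
    expect_false(inmotif)
  }
  expect_error(make_variant_set(g$truth, g$genome, n_pos = 10000L),
               "motif instances")
})

test_that("simulated reads concentrate where coverage is high", {
  spec <- small_spec(seed = 51L, chroms = "chr1", n_peaks = 6L)
  g <- make_genome(spec, "A")
  reads <- make_reads(g$truth, n_reads = 5000L, seed = 4L)
  expect_true(all(reads$end - reads$start == 50L))
  bs <- binding_strength_correlation(reads, g$truth$peaks, g$truth$coverage)
  expect_gt(bs$pearson, 0.5)
})
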