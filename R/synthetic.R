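# Synthetic two-species planted-motif genomes with peak-shaped coverage.
#
# The generator emulates the statistical structure the method assumes: two
# species share one binding motif (PWM) but differ in background composition
# (a species-specific 3-mer table realised as a 2nd-order Markov chain) and
# in a species-private repeat element. Peaks carry Gaussian coverage bumps;
# a truncated-at-zero Gaussian noise floor covers the whole genome.

#' Default planted motif
#'
#' A sharp 12-bp PWM (dominant base probability 0.96, information content
#' about 1.8 bits per column — typical of a strong TF motif) around the
#' consensus TGACGTCATTCC. The sharpness is chosen so that an optimal
#' PWM-scan oracle separates planted windows from background nearly
#' perfectly: a planted-motif benchmark is only informative about a model
#' when the task itself is solvable.
#'
#' @return 4 x 12 probability matrix, rows A, C, G, T.
#' @export
default_motif_pwm <- function() {
  consensus <- strsplit("TGACGTCATTCC", "")[[1]]
  m <- matrix(0.04 / 3, 4, length(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 0.96
  m
}

# species-specific 3-mer probability table (named 64-vector summing to 1)
.base4 <- c("A", "C", "G", "T")
.kmer3 <- as.vector(outer(outer(.base4, .base4, paste0), .base4, paste0))

#' Species background 3-mer tables
#'
#' Two deliberately different backgrounds: species A is AT-rich with
#' A/T homopolymer enrichment; species B is GC-rich with CpG depletion and
#' CAG/CTG enrichment. The shared motif plus these shifted backgrounds is
#' the domain gap adversarial adaptation must bridge.
#'
#' @return named list of two named 64-vectors.
#' @export
default_kmer_bias <- function() {
  mk <- function(base_probs, boost = character(), boost_factor = 2,
                 deplete = character(), deplete_factor = 0.25) {
    p <- apply(expand.grid(.base4, .base4, .base4), 1, function(r) {
      base_probs[r[1]] * base_probs[r[2]] * base_probs[r[3]]
    })
    # expand.grid varies the first factor fastest: reorder to .kmer3 order
    names(p) <- paste0(expand.grid(.base4, .base4, .base4)[, 1],
                       expand.grid(.base4, .base4, .base4)[, 2],
                       expand.grid(.base4, .base4, .base4)[, 3])
    p <- p[.kmer3]
    p[names(p) %in% boost] <- p[names(p) %in% boost] * boost_factor
    if (length(deplete)) {
      hit <- vapply(names(p), function(k) any(vapply(deplete, function(d) {
        grepl(d, k)
      }, logical(1))), logical(1))
      p[hit] <- p[hit] * deplete_factor
    }
    p / sum(p)
  }
  list(A = mk(c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
              boost = c("AAA", "TTT", "AAT", "ATT"), boost_factor = 2.5),
       B = mk(c(A = 0.22, C = 0.28, G = 0.28, T = 0.22),
              boost = c("CAG", "CTG", "CCC", "GGG"), boost_factor = 2.5,
              deplete = "CG"))
}

# Species-private repeat elements (~120 bp, text constants). The
# target-species repeat carries a degenerate motif decoy (consensus with
# two mismatches, upper-cased here only for readability) — real repeat
# families harbour decoy TF motif matches, and such species-specific decoy
# context is a major driver of cross-species degradation.
.default_repeats <- function() {
  list(A = list(sequence = paste0("GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTT",
                                  "GGGAGGCCGAGGCGGGCGGATCACGAGGTCAGGAGATCGA",
                                  "GACCATCCTGGCTAACACGGTGAAACCCCGTCTCTACTAA"),
                insertion_rate = 0.03),
       B = list(sequence = paste0("GGGGCTGGAGAGATGGCTCAGTGGTTAAGAGCACCGACTG",
                                  "CTCTTCCGAA", "TGAGGTCATACC",
                                  "TCAAATCCCAGCAACCACAT",
                                  "GGTGGCTCACAACCATCCGTAACGAGATCTGACTCCCTCT"),
                insertion_rate = 0.08))
}

#' Specification of a synthetic two-species study
#'
#' Defaults define the package's standard toy scale: 2 chromosomes x 100 kb
#' per species, 60 peaks, a shared sharp 12-bp motif, species-specific 3-mer
#' backgrounds and private repeat elements.
#'
#' @param genome_length_per_chrom bases per chromosome.
#' @param chrom_names chromosome names.
#' @param motif_pwm 4 x W probability matrix (columns sum to 1).
#' @param n_peaks total peaks per genome (split across chromosomes by length).
#' @param peak_halfwidth Gaussian sigma of the coverage bump, bases; the peak
#'   interval is the summit +/- 2 halfwidths.
#' @param peak_amplitude_range uniform range of the per-binding-site
#'   contribution to the bump height (signal units). A peak with k planted
#'   motif instances has amplitude k times a draw from this range, so
#'   binding strength is determined by sequence (site count), as it is for
#'   real TFs where read counts track binding-site content.
#' @param max_motifs_per_peak sites per peak are drawn uniformly from
#'   1..max_motifs_per_peak.
#' @param background_kmer_bias named list of per-species 3-mer tables.
#' @param repeat_element named list of per-species list(sequence,
#'   insertion_rate); rate is the genome fraction covered by the repeat.
#' @param noise_sd sd of the truncated-at-zero Gaussian noise floor.
#' @param accessibility also generate a chromatin-accessibility track.
#' @param seed master seed.
#' @return list of class "synthetic_spec".
#' @export
synthetic_spec <- function(genome_length_per_chrom = 100000L,
                           chrom_names = c("chr1", "chr2"),
                           motif_pwm = default_motif_pwm(),
                           n_peaks = 60L,
                           peak_halfwidth = 60L,
                           peak_amplitude_range = c(7, 9),
                           max_motifs_per_peak = 4L,
                           background_kmer_bias = default_kmer_bias(),
                           repeat_element = .default_repeats(),
                           noise_sd = 0.5,
                           accessibility = FALSE,
                           seed = 1L) {
  stopifnot(all(abs(colSums(motif_pwm) - 1) < 1e-9),
            2L * peak_halfwidth < 600L,
            all(vapply(repeat_element, function(r) {
              r$insertion_rate >= 0 && r$insertion_rate < 1
            }, logical(1))),
            genome_length_per_chrom >= 10L * 600L,
            length(chrom_names) >= 1)
  structure(list(genome_length_per_chrom = as.integer(genome_length_per_chrom),
                 chrom_names = chrom_names,
                 motif_pwm = motif_pwm,
                 n_peaks = as.integer(n_peaks),
                 peak_halfwidth = as.integer(peak_halfwidth),
                 peak_amplitude_range = peak_amplitude_range,
                 max_motifs_per_peak = as.integer(max_motifs_per_peak),
                 background_kmer_bias = background_kmer_bias,
                 repeat_element = repeat_element,
                 noise_sd = noise_sd,
                 accessibility = isTRUE(accessibility),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sample a 2nd-order Markov chain from a 3-mer table
.sample_background <- function(len, kmer_table) {
  # conditional P(x3 | x1 x2): 16 x 4, rows indexed by (i1-1)*4 + i2
  cond <- matrix(0, 16, 4)
  for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
    cond[(i1 - 1L) * 4L + i2, i3] <-
      kmer_table[paste0(.base4[i1], .base4[i2], .base4[i3])]
  }
  cond <- cond / rowSums(cond)
  ccum <- t(apply(cond, 1, cumsum))
  start2 <- sample.int(16L, 1L)   # uniform start; the chain mixes in a few steps
  out <- integer(len + 2L)
  out[1] <- (start2 - 1L) %/% 4L + 1L
  out[2] <- (start2 - 1L) %% 4L + 1L
  u <- stats::runif(len)
  prev1 <- out[1]; prev2 <- out[2]
  for (i in seq_len(len)) {
    r <- (prev1 - 1L) * 4L + prev2
    b <- 1L + (u[i] > ccum[r, 1]) + (u[i] > ccum[r, 2]) + (u[i] > ccum[r, 3])
    out[i + 2L] <- b
    prev1 <- prev2; prev2 <- b
  }
  paste(.base4[out[3:(len + 2L)]], collapse = "")
}

.sample_motif <- function(pwm) {
  W <- ncol(pwm)
  idx <- vapply(seq_len(W), function(j) {
    sample.int(4L, 1L, prob = pwm[, j])
  }, integer(1))
  paste(rownames(pwm)[idx], collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.splice <- function(s, start0, piece) {
  # replace bases at 0-based start0 .. start0+nchar(piece)-1
  paste0(substr(s, 1L, start0), piece,
         substr(s, start0 + nchar(piece) + 1L, nchar(s)))
}

#' Generate one species' genome, peaks, coverage and truth
#'
#' Deterministic given (spec$seed, species_id). Peaks are non-overlapping
#' Gaussian coverage bumps, each containing one motif instance sampled from
#' the PWM (uniform strand; reverse complement planted on minus). The
#' species' repeat element is inserted outside peaks at its insertion rate.
#'
#' @param spec a [synthetic_spec()].
#' @param species_id name of an entry of `spec$background_kmer_bias`
#'   (default species "A" or "B").
#' @return list(genome, truth) where truth holds peaks, motif_positions,
#'   coverage and optionally accessibility.
#' @export
make_genome <- function(spec, species_id = "A") {
  si <- match(species_id, names(spec$background_kmer_bias))
  if (is.na(si)) stop("unknown species_id: ", species_id)
  set.seed(spec$seed + 7919L * si)
  kmer <- spec$background_kmer_bias[[species_id]]
  rep_el <- spec$repeat_element[[species_id]]
  hw <- spec$peak_halfwidth
  W <- ncol(spec$motif_pwm)
  lens <- rep(spec$genome_length_per_chrom, length(spec$chrom_names))
  names(lens) <- spec$chrom_names
  peaks_per_chrom <- .apportion(spec$n_peaks, lens)

  genome <- list()
  peaks <- list()
  motifs <- list()
  coverage <- list()
  accessibility <- if (spec$accessibility) list() else NULL
  for (ci in seq_along(lens)) {
    chrom <- names(lens)[ci]
    len <- lens[[ci]]
    s <- .sample_background(len, kmer)
    npk <- peaks_per_chrom[ci]
    centers <- .place_nonoverlapping(len, npk, half_extent = 2L * hw + 300L,
                                     margin = 3L * hw)
    pk <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    mt <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                     strand = character(0))
    cov <- numeric(len)
    if (npk > 0) {
      k_sites <- sample.int(spec$max_motifs_per_peak, npk, replace = TRUE)
      amp <- k_sites * stats::runif(npk, spec$peak_amplitude_range[1],
                                    spec$peak_amplitude_range[2])
      pk <- data.frame(chrom = chrom,
                       start = pmax(0L, centers - 2L * hw),
                       end = pmin(len, centers + 2L * hw),
                       score = amp)
      for (i in seq_len(npk)) {
        cen <- centers[i]
        # plant k_sites[i] non-overlapping instances near the summit
        # (motifs concentrate at ChIP-seq summits): first within +/- hw/4,
        # the rest within +/- hw
        placed_at <- integer(0)
        for (ki in seq_len(k_sites[i])) {
          inst <- .sample_motif(spec$motif_pwm)
          strand <- if (stats::runif(1) < 0.5) "+" else "-"
          planted <- if (strand == "+") inst else .revcomp(inst)
          for (try in 1:50) {
            jitter <- if (ki == 1) {
              sample.int(hw %/% 2L, 1L) - hw %/% 4L - 1L
            } else {
              sample.int(2L * hw, 1L) - hw - 1L
            }
            mstart <- cen - W %/% 2L + jitter          # 0-based
            mstart <- max(pk$start[i], min(mstart, pk$end[i] - W))
            if (all(abs(mstart - placed_at) >= W + 2L)) break
            mstart <- NA_integer_
          }
          if (is.na(mstart)) next
          placed_at <- c(placed_at, mstart)
          s <- .splice(s, mstart, planted)
          mt <- rbind(mt, data.frame(chrom = chrom, start = mstart,
                                     end = mstart + W, strand = strand))
        }
        lo <- max(0L, cen - 3L * hw)
        hi <- min(len - 1L, cen + 3L * hw)
        x <- lo:hi
        cov[x + 1L] <- cov[x + 1L] + amp[i] * exp(-0.5 * ((x - cen) / hw)^2)
      }
    }
    # repeat insertions outside peak neighbourhoods
    if (rep_el$insertion_rate > 0) {
      rl <- nchar(rep_el$sequence)
      n_rep <- floor(rep_el$insertion_rate * len / rl)
      forbidden <- if (npk > 0) {
        cbind(pk$start - rl - 600L, pk$end + 600L)
      } else matrix(numeric(0), 0, 2)
      placed <- 0L
      tries <- 0L
      while (placed < n_rep && tries < 50L * n_rep) {
        tries <- tries + 1L
        p0 <- sample.int(len - rl, 1L) - 1L
        if (nrow(forbidden) == 0 ||
            all(p0 >= forbidden[, 2] | p0 <= forbidden[, 1])) {
          s <- .splice(s, p0, rep_el$sequence)
          placed <- placed + 1L
        }
      }
    }
    if (spec$noise_sd > 0) {
      cov <- pmax(0, cov + stats::rnorm(len, 0, spec$noise_sd))
    }
    genome[[chrom]] <- s
    peaks[[chrom]] <- pk
    motifs[[chrom]] <- mt
    coverage[[chrom]] <- cov
    if (spec$accessibility) {
      acc <- numeric(len)
      if (npk > 0) for (i in seq_len(npk)) {
        cen <- centers[i]
        lo <- max(0L, cen - 6L * hw)
        hi <- min(len - 1L, cen + 6L * hw)
        x <- lo:hi
        acc[x + 1L] <- acc[x + 1L] + exp(-0.5 * ((x - cen) / (2 * hw))^2)
      }
      accessibility[[chrom]] <- pmax(0, acc + stats::rnorm(len, 0, 0.05))
    }
  }
  truth <- structure(list(peaks = do.call(rbind, peaks),
                          motif_positions = do.call(rbind, motifs),
                          coverage = coverage,
                          accessibility = accessibility,
                          species = species_id),
                     class = "synthetic_truth")
  rownames(truth$peaks) <- NULL
  rownames(truth$motif_positions) <- NULL
  list(genome = structure(genome, class = "genome_assembly"), truth = truth)
}

# split n items across chromosomes proportional to length
.apportion <- function(n, lens) {
  raw <- n * lens / sum(lens)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    o <- order(raw - out, decreasing = TRUE)
    out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

# uniform non-overlapping centre placement with rejection sampling
.place_nonoverlapping <- function(len, n, half_extent, margin) {
  if (n == 0) return(integer(0))
  lo <- half_extent + margin
  hi <- len - half_extent - margin
  if (hi <= lo || (hi - lo) < n * 2 * half_extent) {
    stop("genome too short to place ", n, " non-overlapping peaks: ",
         "increase genome_length_per_chrom or decrease n_peaks/peak_halfwidth")
  }
  centers <- integer(0)
  tries <- 0L
  while (length(centers) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("failed to place ", n, " non-overlapping peaks after ", tries,
           " draws; the limiting parameter is n_peaks relative to ",
           "genome_length_per_chrom")
    }
    cand <- sample(lo:hi, 1L)
    if (all(abs(cand - centers) >= 2L * half_extent)) {
      centers <- c(centers, cand)
    }
  }
  sort(centers)
}

#' Build a TF-specific variant set from synthetic truth
#'
#' Positives are single-base substitutions inside planted motif instances;
#' negatives are substitutions near a positive (within `ld_radius`) but
#' outside any motif, mimicking linkage-disequilibrium neighbour SNPs.
#'
#' @param truth synthetic truth from [make_genome()].
#' @param genome matching genome assembly.
#' @param n_pos number of positive variants (<= number of motif instances).
#' @param n_neg_per_pos negatives sampled around each positive.
#' @param ld_radius neighbourhood radius in bases.
#' @param seed RNG seed.
#' @return data.frame (chrom, pos, ref, alt, label, group) of class
#'   "variant_table"; `group` ties each positive to its LD neighbours.
#' @export
make_variant_set <- function(truth, genome, n_pos, n_neg_per_pos = 3L,
                             ld_radius = 500L, seed = 1L) {
  mp <- truth$motif_positions
  if (nrow(mp) < n_pos) {
    stop("requested ", n_pos, " positives but truth has only ", nrow(mp),
         " motif instances")
  }
  set.seed(seed)
  pick <- sort(sample.int(nrow(mp), n_pos))
  rows <- list()
  skipped <- 0L
  for (gi in seq_along(pick)) {
    m <- mp[pick[gi], ]
    pos <- m$start + sample.int(m$end - m$start, 1L) - 1L   # 0-based
    ref <- substr(genome[[m$chrom]], pos + 1L, pos + 1L)
    alt <- sample(setdiff(.base4, ref), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = m$chrom, pos = pos, ref = ref, alt = alt,
      label = 1L, group = gi, causal = TRUE)
    # candidate negative positions: near the positive, outside all motifs
    len <- nchar(genome[[m$chrom]])
    lo <- max(0L, pos - ld_radius)
    hi <- min(len - 1L, pos + ld_radius)
    cand <- lo:hi
    mchrom <- mp[mp$chrom == m$chrom, , drop = FALSE]
    inmotif <- rep(FALSE, length(cand))
    for (k in seq_len(nrow(mchrom))) {
      inmotif <- inmotif | (cand >= mchrom$start[k] & cand < mchrom$end[k])
    }
    cand <- cand[!inmotif]
    if (length(cand) == 0) {
      warning("no non-motif base within ld_radius of positive ", gi,
              "; negatives skipped")
      skipped <- skipped + 1L
      next
    }
    npos_here <- sample(cand, min(n_neg_per_pos, length(cand)))
    for (p0 in npos_here) {
      ref2 <- substr(genome[[m$chrom]], p0 + 1L, p0 + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = m$chrom, pos = p0, ref = ref2,
        alt = sample(setdiff(.base4, ref2), 1L),
        label = 0L, group = gi, causal = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped_groups") <- skipped
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Simulate reads proportional to coverage
#'
#' Read start positions are drawn with probability proportional to the truth
#' coverage plus a small uniform floor, so per-peak read counts track peak
#' amplitudes: the synthetic analogue of defining binding strength as reads
#' in peaks.
#'
#' @param truth synthetic truth.
#' @param n_reads total reads.
#' @param read_len read length in bases.
#' @param seed RNG seed.
#' @return data.frame (chrom, start, end), 0-based half-open.
#' @export
make_reads <- function(truth, n_reads = 20000L, read_len = 50L, seed = 1L) {
  set.seed(seed)
  lens <- vapply(truth$coverage, length, integer(1))
  w_chrom <- vapply(truth$coverage, function(v) sum(v) + 0.1 * length(v),
                    numeric(1))
  n_per <- stats::rmultinom(1, n_reads, w_chrom)[, 1]
  out <- list()
  for (chrom in names(truth$coverage)) {
    v <- truth$coverage[[chrom]] + 0.1
    starts <- sample.int(length(v) - read_len, n_per[[chrom]],
                         replace = TRUE, prob = v[seq_len(length(v) - read_len)])
    out[[chrom]] <- data.frame(chrom = chrom, start = starts - 1L,
                               end = starts - 1L + read_len)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
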