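# Readers/writers for the standard formats at the package boundary.
# All interval coordinates inside the package are 0-based half-open (BED
# convention); conversion to 1-based closed happens only at the GRanges
# boundary.

# data.frame (0-based half-open) -> GRanges
.gr0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Write / read a genome as FASTA
#'
#' @param genome named list (or character vector) of chromosome sequences.
#' @param path file path; 60-column wrapped FASTA.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- as.list(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(genome, class = "genome_assembly")
}

#' Write / read intervals as BED
#'
#' Columns beyond chrom/start/end (name, score, strand) are written when
#' present (BED6).
#'
#' @param df data.frame with chrom, start, end (0-based half-open) and
#'   optionally name, score, strand.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if (any(c("name", "score", "strand") %in% names(df))) {
    df$name <- df$name %||% "."
    df$score <- df$score %||% 0
    df$strand <- df$strand %||% "."
    cols <- c(cols, "name", "score", "strand")
  }
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  df
}

#' Write / read a per-base coverage track as bedGraph
#'
#' Runs of equal value are collapsed; values are written fixed-point with 4
#' decimals. Reading requires the genome (for chromosome lengths); missing
#' bases are imputed as 0.
#'
#' @param coverage named list of per-base numeric vectors.
#' @param path file path.
#' @export
write_bedgraph <- function(coverage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(coverage)) {
    v <- round(coverage[[chrom]], 4)
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.4f", chrom, start[keep], end[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome genome assembly giving chromosome lengths.
#' @export
read_bedgraph <- function(path, genome) {
  coverage <- lapply(genome, function(s) numeric(nchar(s)))
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)   # 1-based
  ends <- GenomicRanges::end(gr)
  vals <- gr$score
  for (i in seq_along(gr)) {
    coverage[[chroms[i]]][starts[i]:ends[i]] <- vals[i]
  }
  coverage
}

#' Write / read a variant table as TSV
#'
#' Columns: chrom, pos (0-based), ref, alt, label.
#'
#' @param variants data.frame.
#' @param path file path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(ref = "character", alt = "character"))
}

#' Write / read motifs in MEME minimal format
#'
#' @param pwms named list of 4 x W probability matrices (rows A, C, G, T).
#' @param path file path.
#' @param bg background base frequencies.
#' @export
write_meme <- function(pwms, path, bg = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)), con)
    for (j in seq_len(ncol(m))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m[1, j], m[2, j], m[3, j], m[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability", lines[j])) j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      m <- t(vapply(rows, function(r) {
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      }, numeric(4)))
      mat <- t(m)
      rownames(mat) <- c("A", "C", "G", "T")
      out[[nm]] <- mat
      i <- j + w
    }
    i <- i + 1L
  }
  out
}
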