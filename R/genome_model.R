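# Genome loading, k-mer occurrence index, nested segmentation.
#
# Coordinates are 0-based half-open (BED convention) everywhere in the
# package.  k-mer counts are over both strands via canonicalization
# (lexicographic min of a k-mer and its reverse complement); k-mers spanning
# an N are not indexed.

SEGMENT_SIZES <- c(mb3 = 3e6, kb500 = 5e5)

#' Load a genome and build its k-mer occurrence index
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file and counts every
#' canonical k-mer over both strands.  The resulting index is the substrate
#' for the probe uniqueness screen: a probe is unique when each of its
#' constituent k-mers occurs exactly once genome-wide.
#'
#' @param fasta_path path to a FASTA file.
#' @param k k-mer length for the uniqueness index (default 18; must be >= 8).
#' @return a `GenomeIndex` object: chromosome names, lengths, uppercase
#'   sequences, and per-position canonical k-mer occurrence counts.
#' @export
load_genome <- function(fasta_path, k = 18L) {
  if (!file.exists(fasta_path)) abort_np(paste0("FASTA not found: ", fasta_path), "np_io_error")
  if (k < 8) abort_np("k must be >= 8", "np_param_error")
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0) abort_np("FASTA file contains no records", "np_empty_fasta")
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) abort_np("duplicate chromosome names in FASTA", "np_dup_chrom")
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGTRYSWKMBDHVN]", seqs)))
    abort_np("non-IUPAC characters in sequence", "np_bad_alphabet")
  names(seqs) <- nms
  genome_index(seqs, k = as.integer(k))
}

#' Build a GenomeIndex from in-memory sequences
#'
#' @param sequences named character vector of chromosome sequences.
#' @param k k-mer length (default 18).
#' @return a `GenomeIndex`.
#' @export
genome_index <- function(sequences, k = 18L) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)))
  k <- as.integer(k)
  if (k < 8) abort_np("k must be >= 8", "np_param_error")
  sequences <- toupper(sequences)
  pos_counts <- cpp_kmer_position_counts(sequences, k)
  names(pos_counts) <- names(sequences)
  structure(list(chrom_names = names(sequences),
                 chrom_lengths = setNames(nchar(sequences), names(sequences)),
                 sequences = sequences,
                 k = k,
                 pos_counts = pos_counts),
            class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp, k =", x$k, "\n")
  for (nm in x$chrom_names)
    cat("  ", nm, ": ", format(x$chrom_lengths[[nm]], big.mark = ","), " bp\n",
        sep = "")
  invisible(x)
}

#' Query the genome-wide occurrence count of one k-mer
#'
#' Counts occurrences over both strands (the canonical count); a palindromic
#' k-mer therefore counts twice per genomic site.
#'
#' @param genome a `GenomeIndex`.
#' @param kmer a single A/C/G/T string of the index's k (any length 1..31 is
#'   accepted for ad-hoc queries).
#' @return integer occurrence count (0 if absent).
#' @export
kmer_count <- function(genome, kmer) {
  stopifnot(inherits(genome, "GenomeIndex"), is.character(kmer),
            length(kmer) == 1)
  cpp_kmer_count_query(genome$sequences, toupper(kmer))
}

#' Partition a chromosome into fixed-size segments
#'
#' Tiles `[0, chrom_length)` with 3 Mb (`"mb3"`) or 500 kb (`"kb500"`)
#' segments; the last segment absorbs the remainder.  Segment indices are
#' chromosome-wide 0-based ordinals, so every kb500 segment with index j lies
#' inside the mb3 segment with index `j %/% 6`.
#'
#' @param chrom_length chromosome length in bp (> 0).
#' @param level `"mb3"` or `"kb500"`.
#' @param chrom chromosome name attached to the output rows.
#' @return data.frame with columns chrom, level, index, start, end
#'   (0-based half-open).
#' @export
segment_chromosome <- function(chrom_length, level = c("mb3", "kb500"),
                               chrom = "chr") {
  level <- match.arg(level)
  if (!is.numeric(chrom_length) || length(chrom_length) != 1 ||
      chrom_length <= 0)
    abort_np("chrom_length must be a positive number", "np_param_error")
  size <- SEGMENT_SIZES[[level]]
  starts <- seq(0, chrom_length - 1, by = size)
  ends <- pmin(starts + size, chrom_length)
  data.frame(chrom = chrom, level = level, index = seq_along(starts) - 1L,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Segment every chromosome of a genome
#'
#' @param genome a `GenomeIndex`.
#' @param level `"mb3"` or `"kb500"`.
#' @return data.frame of segments across all chromosomes.
#' @export
segment_genome <- function(genome, level = c("mb3", "kb500")) {
  level <- match.arg(level)
  do.call(rbind, lapply(genome$chrom_names, function(nm)
    segment_chromosome(genome$chrom_lengths[[nm]], level, chrom = nm)))
}

#' Write segments as BED6
#'
#' Names follow `<chrom>_<level>_<index>`; score 0, strand "+".
#'
#' @param segments data.frame from [segment_chromosome()] / [segment_genome()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = format(segments$start, scientific = FALSE, trim = TRUE),
                    end = format(segments$end, scientific = FALSE, trim = TRUE),
                    name = paste(segments$chrom, segments$level,
                                 segments$index, sep = "_"),
                    score = 0L, strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# segment assignment of a 0-based position
segment_index_of <- function(start, level) {
  as.integer(start %/% SEGMENT_SIZES[[level]])
}
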