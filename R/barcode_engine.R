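# Orthogonal barcode generation, 150-nt primary-oligo assembly with the
# nested barcode layout, and in-silico sub-pool amplification.
#
# Slot order (5' to 3'): chrom_fwd | mb3 | kb500 | homology | seg_specific |
# chrom_rev.  The two chromosome barcodes double as the PCR primer sites at
# the oligo termini; the chrom_rev slot stores the reverse complement of the
# reverse-primer binding site so that the (chrom_fwd, chrom_rev) primer pair
# amplifies the oligo.  The seg_specific slot carries the extra per-500 kb
# barcode that is reserved for boosting detection and is otherwise unused.

BARCODE_ROLES <- c("chrom_fwd", "chrom_rev", "mb3", "kb500", "seg_specific")

#' Primary-oligo layout
#'
#' @param chrom_fwd,mb3,kb500,homology,seg_specific,chrom_rev slot lengths
#'   in nt (defaults 20, 23, 23, 42, 22, 20; total 150).
#' @return a `LibraryLayout` list with `slots` (named lengths in 5'->3'
#'   order) and `total_length`.
#' @export
library_layout <- function(chrom_fwd = 20L, mb3 = 23L, kb500 = 23L,
                           homology = 42L, seg_specific = 22L,
                           chrom_rev = 20L) {
  slots <- c(chrom_fwd = as.integer(chrom_fwd), mb3 = as.integer(mb3),
             kb500 = as.integer(kb500), homology = as.integer(homology),
             seg_specific = as.integer(seg_specific),
             chrom_rev = as.integer(chrom_rev))
  if (any(slots < 1)) abort_np("all slot lengths must be positive", "np_param_error")
  structure(list(slots = slots, total_length = sum(slots)),
            class = "LibraryLayout")
}

# slot length for a barcode role under a layout
role_slot_length <- function(layout, role) {
  slot <- if (role == "seg_specific") "seg_specific" else role
  layout$slots[[slot]]
}

#' Barcode design constraints
#'
#' @param min_hamming minimum pairwise Hamming distance among same-role,
#'   same-length barcodes (default 8).
#' @param gc_min,gc_max GC window (defaults 0.40, 0.60).
#' @param max_shared_kmer longest barcode substring allowed to occur in the
#'   target genome; default 14, i.e. no barcode 15-mer may occur.
#' @param max_hairpin_stem longest self-complementary stem (default 6).
#' @param max_3p_complementarity longest mutual 3'-end complementarity with
#'   any previously accepted barcode, bp (default 4).
#' @param attempts_per_barcode rejection-sampling budget per barcode
#'   (default 2000).
#' @return a `BarcodeConstraints` list.
#' @export
barcode_constraints <- function(min_hamming = 8L, gc_min = 0.40,
                                gc_max = 0.60, max_shared_kmer = 14L,
                                max_hairpin_stem = 6L,
                                max_3p_complementarity = 4L,
                                attempts_per_barcode = 2000L) {
  structure(list(min_hamming = as.integer(min_hamming), gc_min = gc_min,
                 gc_max = gc_max, max_shared_kmer = as.integer(max_shared_kmer),
                 max_hairpin_stem = as.integer(max_hairpin_stem),
                 max_3p_complementarity = as.integer(max_3p_complementarity),
                 attempts_per_barcode = as.integer(attempts_per_barcode)),
            class = "BarcodeConstraints")
}

# TRUE iff candidate barcode satisfies the genome-sharing constraint
barcode_clears_genome <- function(seq, genome, max_shared) {
  if (is.null(genome)) return(TRUE)
  klen <- max_shared + 1L
  n <- nchar(seq)
  if (n < klen) return(TRUE)
  kmers <- substring(seq, seq_len(n - klen + 1), seq_len(n - klen + 1) + klen - 1)
  all(vapply(kmers, function(km)
    cpp_kmer_count_query(genome$sequences, km) == 0L, logical(1)))
}

#' Generate orthogonal barcodes for one role
#'
#' Rejection sampling under pairwise Hamming, GC, hairpin, 3'-end
#' cross-complementarity, and genome-exclusion constraints.  Deterministic
#' for a fixed seed; errors once the attempt budget is exhausted, naming the
#' constraint that failed most often.
#'
#' @param n number of barcodes.
#' @param role one of `r paste(BARCODE_ROLES, collapse = ", ")`.
#' @param constraints a `BarcodeConstraints`.
#' @param genome optional `GenomeIndex` the barcodes must avoid.
#' @param seed integer RNG seed (mandatory).
#' @param layout a `LibraryLayout` supplying the slot length.
#' @param existing optional character vector of already-accepted barcode
#'   sequences (any role) checked for 3'-end complementarity.
#' @return data.frame: id, role, sequence.
#' @export
generate_barcodes <- function(n, role, constraints = barcode_constraints(),
                              genome = NULL, seed, layout = library_layout(),
                              existing = character(0)) {
  stopifnot(n >= 1, role %in% BARCODE_ROLES)
  if (missing(seed)) abort_np("seed is mandatory", "np_param_error")
  len <- role_slot_length(layout, role)
  if (constraints$min_hamming > len)
    abort_np("min_hamming exceeds the slot length", "np_infeasible")
  if (log(n) > len * log(4))
    abort_np(sprintf("cannot place %d distinct %d-mers", n, len),
             "np_infeasible")
  set.seed(seed)
  accepted <- character(0)
  fails <- c(gc = 0L, hairpin = 0L, hamming = 0L, genome = 0L, cross3p = 0L)
  budget <- constraints$attempts_per_barcode * n
  attempts <- 0L
  while (length(accepted) < n) {
    if (attempts >= budget) {
      worst <- names(which.max(fails))
      abort_np(sprintf(
        "barcode generation infeasible: %d/%d placed after %d attempts (most violated bound: %s)",
        length(accepted), n, attempts, worst), "np_infeasible")
    }
    attempts <- attempts + 1L
    cand <- random_dna(1, len, gc = 0.5)
    gc <- gc_fraction(cand)
    if (gc < constraints$gc_min || gc > constraints$gc_max) {
      fails["gc"] <- fails["gc"] + 1L; next
    }
    if (cpp_longest_stem(cand, 3L) > constraints$max_hairpin_stem) {
      fails["hairpin"] <- fails["hairpin"] + 1L; next
    }
    if (length(accepted) &&
        any(vapply(accepted, function(b) hamming(cand, b), integer(1)) <
            constraints$min_hamming)) {
      fails["hamming"] <- fails["hamming"] + 1L; next
    }
    others <- c(accepted, existing)
    if (length(others) &&
        any(vapply(others, function(b)
          max(three_prime_complementarity(cand, b),
              three_prime_complementarity(b, cand)), integer(1)) >
          constraints$max_3p_complementarity)) {
      fails["cross3p"] <- fails["cross3p"] + 1L; next
    }
    if (!barcode_clears_genome(cand, genome, constraints$max_shared_kmer)) {
      fails["genome"] <- fails["genome"] + 1L; next
    }
    accepted <- c(accepted, cand)
  }
  data.frame(id = sprintf("%s_%02d", role, seq_len(n) - 1L),
             role = role, sequence = accepted, stringsAsFactors = FALSE)
}

#' Generate the complete barcode set for a genome
#'
#' One chrom_fwd and one chrom_rev barcode per chromosome, one mb3 barcode
#' per 3 Mb segment, one kb500 and one seg_specific barcode per 500 kb
#' segment.  All roles are drawn under the same constraints and checked for
#' 3'-end cross-complementarity across roles.
#'
#' @param genome a `GenomeIndex`.
#' @param constraints a `BarcodeConstraints`.
#' @param seed integer seed.
#' @param layout a `LibraryLayout`.
#' @return a `BarcodeSet` data.frame: id, role, chrom, seg_index, sequence.
#' @export
generate_barcode_set <- function(genome, constraints = barcode_constraints(),
                                 seed, layout = library_layout()) {
  stopifnot(inherits(genome, "GenomeIndex"))
  if (missing(seed)) abort_np("seed is mandatory", "np_param_error")
  mb3 <- segment_genome(genome, "mb3")
  kb500 <- segment_genome(genome, "kb500")
  want <- list(
    chrom_fwd = data.frame(chrom = genome$chrom_names, seg_index = NA_integer_),
    chrom_rev = data.frame(chrom = genome$chrom_names, seg_index = NA_integer_),
    mb3 = data.frame(chrom = mb3$chrom, seg_index = mb3$index),
    kb500 = data.frame(chrom = kb500$chrom, seg_index = kb500$index),
    seg_specific = data.frame(chrom = kb500$chrom, seg_index = kb500$index))
  existing <- character(0)
  out <- list()
  for (i in seq_along(want)) {
    role <- names(want)[i]
    meta <- want[[i]]
    bc <- generate_barcodes(nrow(meta), role, constraints, genome,
                            seed = seed + i, layout = layout,
                            existing = existing)
    bc$chrom <- meta$chrom
    bc$seg_index <- meta$seg_index
    bc$id <- ifelse(is.na(meta$seg_index),
                    paste(role, meta$chrom, sep = "|"),
                    paste(role, meta$chrom, meta$seg_index, sep = "|"))
    existing <- c(existing, bc$sequence)
    out[[role]] <- bc
  }
  res <- do.call(rbind, out)[, c("id", "role", "chrom", "seg_index", "sequence")]
  rownames(res) <- NULL
  class(res) <- c("BarcodeSet", "data.frame")
  res
}

# fetch one barcode row by role + chrom (+ segment index)
barcode_lookup <- function(barcodes, role, chrom, seg_index = NA) {
  hit <- barcodes$role == role & barcodes$chrom == chrom &
    (if (is.na(seg_index)) is.na(barcodes$seg_index)
     else !is.na(barcodes$seg_index) & barcodes$seg_index == seg_index)
  row <- barcodes[hit, , drop = FALSE]
  if (nrow(row) != 1)
    abort_np(sprintf("no unique %s barcode for %s segment %s", role, chrom,
                     as.character(seg_index)), "np_missing_barcode")
  row
}

#' Assemble one 150-nt primary oligo
#'
#' Concatenates chrom_fwd | mb3 | kb500 | homology | seg_specific |
#' revcomp(chrom_rev barcode).  Segment assignments are derived from the
#' candidate start (`floor(start / segment size)`) and must match the
#' supplied barcodes.
#'
#' @param candidate one-row data.frame (chrom, start, sequence).
#' @param barcodes a `BarcodeSet`.
#' @param layout a `LibraryLayout`.
#' @return one-row data.frame: full_sequence, chrom, start, mb3_index,
#'   kb500_index, and the five barcode ids.
#' @export
assemble_oligo <- function(candidate, barcodes, layout = library_layout()) {
  stopifnot(nrow(candidate) == 1)
  if (nchar(candidate$sequence) != layout$slots[["homology"]])
    abort_np("candidate sequence does not fill the homology slot",
             "np_param_error")
  cm <- candidate$chrom
  i3 <- segment_index_of(candidate$start, "mb3")
  i5 <- segment_index_of(candidate$start, "kb500")
  b_cf <- barcode_lookup(barcodes, "chrom_fwd", cm)
  b_cr <- barcode_lookup(barcodes, "chrom_rev", cm)
  b_m3 <- barcode_lookup(barcodes, "mb3", cm, i3)
  b_k5 <- barcode_lookup(barcodes, "kb500", cm, i5)
  b_ss <- barcode_lookup(barcodes, "seg_specific", cm, i5)
  for (b in list(b_cf, b_cr)) if (nchar(b$sequence) != layout$slots[["chrom_fwd"]])
    abort_np("chromosome barcode length does not match the layout slot",
             "np_param_error")
  full <- paste0(b_cf$sequence, b_m3$sequence, b_k5$sequence,
                 candidate$sequence, b_ss$sequence, revcomp(b_cr$sequence))
  stopifnot(nchar(full) == layout$total_length)
  data.frame(full_sequence = full, chrom = cm, start = candidate$start,
             mb3_index = i3, kb500_index = i5,
             chrom_fwd_id = b_cf$id, mb3_id = b_m3$id, kb500_id = b_k5$id,
             seg_specific_id = b_ss$id, chrom_rev_id = b_cr$id,
             stringsAsFactors = FALSE)
}

#' Assemble the full primary-oligo library
#'
#' @param candidates data.frame of selected candidates (chrom, start,
#'   sequence).
#' @param barcodes a `BarcodeSet` covering every touched segment.
#' @param layout a `LibraryLayout`.
#' @return an `OligoLibrary` data.frame (one row per primary oligo) with the
#'   layout attached as attribute `layout`.
#' @export
assemble_library <- function(candidates, barcodes, layout = library_layout()) {
  rows <- lapply(seq_len(nrow(candidates)), function(i)
    assemble_oligo(candidates[i, , drop = FALSE], barcodes, layout))
  lib <- do.call(rbind, rows)
  lib$homology <- candidates$sequence
  rownames(lib) <- NULL
  attr(lib, "layout") <- layout
  class(lib) <- c("OligoLibrary", "data.frame")
  lib
}

#' Simulate PCR sub-pool amplification with a primer pair
#'
#' Exact-match model: an oligo amplifies iff its 5' terminus equals the
#' forward primer and its 3' terminus equals the reverse complement of the
#' reverse primer.
#'
#' @param library an `OligoLibrary` (or data.frame with `full_sequence`).
#' @param fwd_primer,rev_primer primer sequences at the slot lengths.
#' @return the amplified subset of `library` (possibly empty).
#' @export
simulate_pcr <- function(library, fwd_primer, rev_primer) {
  if (nrow(library) == 0) return(library)
  fl <- nchar(fwd_primer)
  rl <- nchar(rev_primer)
  seqs <- library$full_sequence
  n <- nchar(seqs)
  hit <- substr(seqs, 1L, fl) == toupper(fwd_primer) &
    substring(seqs, n - rl + 1L) == revcomp(toupper(rev_primer))
  library[hit, , drop = FALSE]
}

#' Select a sub-pool by metadata at a hierarchy level
#'
#' @param library an `OligoLibrary`.
#' @param level `"chromosome"`, `"mb3"`, or `"kb500"`.
#' @param chrom chromosome name.
#' @param index segment index (ignored for chromosome level).
#' @return the matching subset of `library`.
#' @export
select_subpool <- function(library, level = c("chromosome", "mb3", "kb500"),
                           chrom, index = NULL) {
  level <- match.arg(level)
  if (!chrom %in% library$chrom)
    abort_np(paste0("unknown chromosome in library: ", chrom),
             "np_unknown_segment")
  hit <- library$chrom == chrom
  if (level != "chromosome") {
    if (is.null(index)) abort_np("segment index required", "np_param_error")
    col <- if (level == "mb3") "mb3_index" else "kb500_index"
    if (!any(library[[col]][hit] == index))
      abort_np(sprintf("no oligos in %s segment %s:%d", level, chrom, index),
               "np_unknown_segment")
    hit <- hit & library[[col]] == index
  }
  library[hit, , drop = FALSE]
}

#' Amplify the sub-pool of one chromosome via its primer pair
#'
#' Convenience wrapper looking up the chromosome's fwd/rev barcodes and
#' running [simulate_pcr()].
#'
#' @param library an `OligoLibrary`.
#' @param barcodes the `BarcodeSet` used to assemble it.
#' @param chrom chromosome name.
#' @return the amplified subset.
#' @export
amplify_chromosome <- function(library, barcodes, chrom) {
  fwd <- barcode_lookup(barcodes, "chrom_fwd", chrom)$sequence
  rev <- barcode_lookup(barcodes, "chrom_rev", chrom)$sequence
  simulate_pcr(library, fwd, rev)
}

#' Write / read a primary-oligo library as FASTA
#'
#' Record ids follow `<chrom>:<start>-<end>|mb3=<i>|kb500=<j>`.
#'
#' @param library an `OligoLibrary`.
#' @param path file path.
#' @param layout a `LibraryLayout` (for re-attachment on read).
#' @return `write_library_fasta`: the path, invisibly; `read_library_fasta`:
#'   a data.frame with full_sequence and parsed assignments.
#' @export
write_library_fasta <- function(library, path) {
  layout <- attr(library, "layout") %||% library_layout()
  hl <- layout$slots[["homology"]]
  ids <- sprintf("%s:%d-%d|mb3=%d|kb500=%d", library$chrom, library$start,
                 library$start + hl, library$mb3_index, library$kb500_index)
  writeLines(paste0(">", ids, "\n", library$full_sequence), path)
  invisible(path)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(path, layout = library_layout()) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  m <- regmatches(ids, regexec(
    "^([^:]+):([0-9]+)-([0-9]+)\\|mb3=([0-9]+)\\|kb500=([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 6
  if (any(bad)) abort_np("malformed library FASTA record id", "np_io_error")
  out <- data.frame(full_sequence = as.character(ss),
                    chrom = vapply(m, `[`, character(1), 2),
                    start = as.numeric(vapply(m, `[`, character(1), 3)),
                    mb3_index = as.integer(vapply(m, `[`, character(1), 5)),
                    kb500_index = as.integer(vapply(m, `[`, character(1), 6)),
                    stringsAsFactors = FALSE)
  attr(out, "layout") <- layout
  class(out) <- c("OligoLibrary", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write barcodes as a TSV manifest
#'
#' @param barcodes a `BarcodeSet`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_barcodes_tsv <- function(barcodes, path) {
  write.table(as.data.frame(barcodes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
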