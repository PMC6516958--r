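# Mining 42-nt homology candidates under four filter classes:
# (1) genome-wide uniqueness of every constituent k-mer,
# (2) Tm and GC windows,
# (3) repetitive-stretch exclusion (homopolymers, dinucleotide tandems),
# (4) secondary-structure exclusion (longest self-complementary hairpin stem).

#' Probe mining parameters
#'
#' Defaults follow common Oligopaint practice; the screening Tm window is
#' defined on the salt-corrected, formamide-free Tm (formamide_pct is
#' carried for reporting the in-buffer Tm, not applied during screening).
#'
#' @param homology_length candidate length in nt (default 42).
#' @param gc_min,gc_max GC fraction window (defaults 0.30, 0.70).
#' @param tm_min,tm_max Tm window in degC under `na_conc` (defaults 60, 80).
#' @param na_conc monovalent salt, molar (default 0.39, i.e. 2x SSC).
#' @param oligo_conc total strand concentration, molar (default 5e-8).
#' @param formamide_pct hybridization formamide percent (default 50);
#'   informational for the screen, used by [melting_temperature()] when
#'   in-buffer Tm is requested.
#' @param formamide_coef degC depression per percent formamide (default 0.65).
#' @param k_unique uniqueness k-mer length (default 18).
#' @param max_kmer_hits maximum genome-wide count allowed for each
#'   constituent k-mer (default 1 = strictly unique).
#' @param max_homopolymer longest allowed single-base run (default 5).
#' @param max_dinuc_repeat longest allowed dinucleotide tandem, in units
#'   (default 4).
#' @param max_hairpin_stem longest allowed self-complementary stem, bp
#'   (default 7; loops shorter than `min_loop` nt cannot close a stem).
#' @param min_loop minimum hairpin loop length, nt (default 3).
#' @return a `ProbeParams` list.
#' @export
probe_params <- function(homology_length = 42L, gc_min = 0.30, gc_max = 0.70,
                         tm_min = 60, tm_max = 80, na_conc = 0.39,
                         oligo_conc = 5e-8, formamide_pct = 50,
                         formamide_coef = 0.65, k_unique = 18L,
                         max_kmer_hits = 1L, max_homopolymer = 5L,
                         max_dinuc_repeat = 4L, max_hairpin_stem = 7L,
                         min_loop = 3L) {
  p <- list(homology_length = as.integer(homology_length),
            gc_min = gc_min, gc_max = gc_max, tm_min = tm_min,
            tm_max = tm_max, na_conc = na_conc, oligo_conc = oligo_conc,
            formamide_pct = formamide_pct, formamide_coef = formamide_coef,
            k_unique = as.integer(k_unique),
            max_kmer_hits = as.integer(max_kmer_hits),
            max_homopolymer = as.integer(max_homopolymer),
            max_dinuc_repeat = as.integer(max_dinuc_repeat),
            max_hairpin_stem = as.integer(max_hairpin_stem),
            min_loop = as.integer(min_loop))
  if (!(p$gc_min >= 0 && p$gc_min < p$gc_max && p$gc_max <= 1))
    abort_np("need 0 <= gc_min < gc_max <= 1", "np_param_error")
  if (!(p$tm_min < p$tm_max)) abort_np("need tm_min < tm_max", "np_param_error")
  if (p$homology_length < p$k_unique)
    abort_np("homology_length must be >= k_unique", "np_param_error")
  class(p) <- "ProbeParams"
  p
}

#' Longest self-complementary hairpin stem of a sequence
#'
#' Longest s such that two substrings A and B of the sequence, separated by
#' at least `min_loop` nt, satisfy B = revcomp(A).
#'
#' @param sequence A/C/G/T string.
#' @param min_loop minimum loop length in nt (default 3).
#' @return integer stem length in bp.
#' @export
longest_hairpin_stem <- function(sequence, min_loop = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  cpp_longest_stem(toupper(sequence), as.integer(min_loop))
}

# repeat checks on a single sequence (R reference path)
has_homopolymer <- function(sequence, max_run) {
  grepl(paste0("([ACGTN])\\1{", max_run, ",}"), sequence)
}

has_dinuc_repeat <- function(sequence, max_units) {
  # a tandem repeat of any 2-mer with more than max_units units; period-2
  # runs of a single base are caught by the homopolymer rule as well
  pats <- outer(BASES, BASES, function(a, b) paste0(a, b))
  any(vapply(as.vector(pats), function(d)
    grepl(paste0("(", d, "){", max_units + 1, ",}"), sequence), logical(1)))
}

#' Evaluate one candidate sequence against all probe filters
#'
#' Each filter component is computed independently; `overall` is their
#' conjunction.  Sequences containing N fail `passes_unique` by convention.
#'
#' @param sequence string of length `params$homology_length`.
#' @param genome a `GenomeIndex` (supplies the uniqueness screen).
#' @param params a `ProbeParams`.
#' @return a `FilterVerdict` list: passes_unique, passes_gc, passes_tm,
#'   passes_repeat, passes_structure, overall, plus the measured tm and gc.
#' @export
evaluate_probe <- function(sequence, genome, params = probe_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) != params$homology_length)
    abort_np(sprintf("sequence length %d != homology_length %d",
                     nchar(sequence), params$homology_length),
             "np_param_error")
  k <- params$k_unique
  clean <- !grepl("[^ACGT]", sequence)
  passes_unique <- FALSE
  if (clean) {
    kmers <- substring(sequence, seq_len(nchar(sequence) - k + 1),
                       seq_len(nchar(sequence) - k + 1) + k - 1)
    hits <- vapply(kmers, function(km) kmer_count(genome, km), integer(1))
    passes_unique <- all(hits >= 1) && all(hits <= params$max_kmer_hits)
  }
  gc <- gc_fraction(sequence)
  passes_gc <- gc >= params$gc_min && gc <= params$gc_max
  tm <- if (clean)
    melting_temperature(sequence, tm_conditions(params$na_conc,
                                                params$oligo_conc))
  else NA_real_
  passes_tm <- clean && tm >= params$tm_min && tm <= params$tm_max
  passes_repeat <- !has_homopolymer(sequence, params$max_homopolymer) &&
    !has_dinuc_repeat(sequence, params$max_dinuc_repeat)
  passes_structure <-
    longest_hairpin_stem(sequence, params$min_loop) <= params$max_hairpin_stem
  out <- list(passes_unique = passes_unique, passes_gc = passes_gc,
              passes_tm = passes_tm, passes_repeat = passes_repeat,
              passes_structure = passes_structure,
              overall = passes_unique && passes_gc && passes_tm &&
                passes_repeat && passes_structure,
              tm = tm, gc = gc)
  class(out) <- "FilterVerdict"
  out
}

#' Scan a chromosome for candidate probes
#'
#' Evaluates every start position (stride 1), keeps windows passing all four
#' filter classes, then greedily thins left-to-right to non-overlapping
#' candidates.  Deterministic: identical genome and params give an identical
#' candidate list.
#'
#' @param genome a `GenomeIndex` built with `k = params$k_unique`.
#' @param chrom chromosome name.
#' @param params a `ProbeParams`.
#' @param thin if TRUE (default) greedily keep the leftmost candidate, then
#'   the next one starting at or after its end, and so on; if FALSE return
#'   all (overlapping) passing windows.
#' @return data.frame of `CandidateProbe`s: chrom, start (0-based), strand
#'   ("+"), sequence, tm, gc — sorted by start.
#' @export
scan_candidates <- function(genome, chrom, params = probe_params(),
                            thin = TRUE) {
  stopifnot(inherits(genome, "GenomeIndex"))
  if (!chrom %in% genome$chrom_names)
    abort_np(paste0("unknown chromosome: ", chrom), "np_unknown_chrom")
  if (genome$k != params$k_unique)
    abort_np(sprintf("genome index k (%d) != params$k_unique (%d)",
                     genome$k, params$k_unique), "np_param_error")
  seq <- genome$sequences[[chrom]]
  hits <- cpp_scan_windows(seq, genome$pos_counts[[chrom]],
                           params$homology_length, params$k_unique,
                           params$gc_min, params$gc_max,
                           params$tm_min, params$tm_max,
                           params$na_conc, params$oligo_conc,
                           params$max_kmer_hits, params$max_homopolymer,
                           params$max_dinuc_repeat, params$max_hairpin_stem,
                           params$min_loop)
  starts <- hits$start
  if (length(starts) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), sequence = character(0),
                      tm = numeric(0), gc = numeric(0),
                      stringsAsFactors = FALSE))
  keep <- seq_along(starts)
  if (thin && length(starts) > 1) {
    keep <- integer(0)
    next_free <- -1
    for (i in seq_along(starts)) {
      if (starts[i] >= next_free) {
        keep <- c(keep, i)
        next_free <- starts[i] + params$homology_length
      }
    }
  }
  starts <- starts[keep]
  data.frame(chrom = rep(chrom, length(starts)), start = starts,
             strand = rep("+", length(starts)),
             sequence = substring(seq, starts + 1,
                                  starts + params$homology_length),
             tm = hits$tm[keep], gc = hits$gc[keep],
             stringsAsFactors = FALSE)
}

#' Scan all chromosomes of a genome for candidate probes
#'
#' @inheritParams scan_candidates
#' @return data.frame of candidates across chromosomes.
#' @export
mine_genome <- function(genome, params = probe_params(), thin = TRUE) {
  do.call(rbind, lapply(genome$chrom_names, function(nm)
    scan_candidates(genome, nm, params, thin)))
}

#' Write candidate probes as BED6
#'
#' @param candidates data.frame from [scan_candidates()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  n <- nrow(candidates)
  len <- if (n > 0) nchar(candidates$sequence[1]) else 0L
  bed <- data.frame(chrom = candidates$chrom,
                    start = format(candidates$start, scientific = FALSE, trim = TRUE),
                    end = format(candidates$start + len, scientific = FALSE, trim = TRUE),
                    name = sprintf("probe_%d", seq_len(n)),
                    score = 0L, strand = candidates$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
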