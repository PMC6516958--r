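# shared fixture: small 2-chromosome genome, mined + selected + assembled
make_library_fixture <- function() {
  gs <- simulate_genome(sim_genome_params(n_chrom = 2, chrom_length = 4e4,
                                          seed = 41))
  g <- genome_index(gs$sequences, k = 18)
  cand <- mine_genome(g)
  sel <- subsample(cand, selection_params(step = 5))
  bc <- generate_barcode_set(g, seed = 42)
  lib <- assemble_library(sel, bc)
  list(genome = g, candidates = sel, barcodes = bc, library = lib)
}

FX <- make_library_fixture()

test_that("layout slots sum to 150 and assembly decomposes exactly", {
  ly <- library_layout()
  expect_equal(ly$total_length, 150L)
  expect_equal(unname(ly$slots[["homology"]]), 42L)

  lib <- FX$library
  expect_true(all(nchar(lib$full_sequence) == 150))
  # slot decomposition recovers barcodes and homology
  bc <- FX$barcodes
  off <- cumsum(c(0, ly$slots))
  for (i in sample(nrow(lib), 5)) {
    row <- lib[i, ]
    sl <- substring(row$full_sequence, off[-length(off)] + 1, off[-1])
    expect_equal(sl[1], bc$sequence[bc$id == row$chrom_fwd_id])
    expect_equal(sl[2], bc$sequence[bc$id == row$mb3_id])
    expect_equal(sl[3], bc$sequence[bc$id == row$kb500_id])
    expect_equal(sl[4], row$homology)
    expect_equal(sl[5], bc$sequence[bc$id == row$seg_specific_id])
    expect_equal(sl[6], rc1(bc$sequence[bc$id == row$chrom_rev_id]))
  }
})

test_that("segment assignments follow floor(start / segment size)", {
  # a candidate at chrI:1,250,000 sits in mb3 segment 0 (0-3 Mb) and kb500
  # segment 2 (1.0-1.5 Mb)
  long_bc <- data.frame(
    id = c("chrom_fwd|chrI", "chrom_rev|chrI", "mb3|chrI|0", "kb500|chrI|2",
           "seg_specific|chrI|2"),
    role = c("chrom_fwd", "chrom_rev", "mb3", "kb500", "seg_specific"),
    chrom = "chrI", seg_index = c(NA, NA, 0L, 2L, 2L),
    sequence = c(strrep("AC", 10), strrep("GT", 10), paste0(strrep("AG", 11), "A"),
                 paste0(strrep("TC", 11), "T"), strrep("CT", 11)),
    stringsAsFactors = FALSE)
  cand <- data.frame(chrom = "chrI", start = 1250000,
                     sequence = paste0(strrep("ACGT", 10), "AC"))
  oligo <- assemble_oligo(cand, long_bc)
  expect_equal(oligo$mb3_index, 0L)
  expect_equal(oligo$kb500_index, 2L)
  expect_equal(nchar(oligo$full_sequence), 150)

  # wrong-segment barcode is an error
  bad <- long_bc
  bad$seg_index[bad$role == "kb500"] <- 1L
  bad$id[bad$role == "kb500"] <- "kb500|chrI|1"
  expect_error(assemble_oligo(cand, bad), class = "np_missing_barcode")
})

test_that("generated barcodes satisfy their constraints (oracle-verified)", {
  g <- FX$genome
  cons <- barcode_constraints()
  bc <- generate_barcodes(40, "mb3", cons, g, seed = 5)
  expect_equal(nrow(bc), 40)
  expect_true(all(nchar(bc$sequence) == 23))
  expect_gte(oracle_min_hamming(bc$sequence), cons$min_hamming)
  gcs <- gc_fraction(bc$sequence)
  expect_true(all(gcs >= cons$gc_min & gcs <= cons$gc_max))
  for (s in bc$sequence)
    expect_lte(oracle_stem(s), cons$max_hairpin_stem)
  # no barcode 15-mer occurs in the genome (scan check)
  for (s in bc$sequence) {
    for (j in 1:(nchar(s) - 15 + 1))
      expect_equal(kmer_count(g, substr(s, j, j + 14)), 0)
  }
  # determinism
  bc2 <- generate_barcodes(40, "mb3", cons, g, seed = 5)
  expect_identical(bc, bc2)
})

test_that("single-barcode and pigeonhole-infeasible requests behave", {
  cons <- barcode_constraints(min_hamming = 1L)
  one <- generate_barcodes(1, "kb500", cons, seed = 7)
  expect_equal(nrow(one), 1)
  tiny <- library_layout(kb500 = 2L)
  expect_error(
    generate_barcodes(20, "kb500", barcode_constraints(min_hamming = 1L),
                      seed = 7, layout = tiny),
    class = "np_infeasible")
})

test_that("simulate_pcr equals metadata selection for every chromosome", {
  lib <- FX$library
  bc <- FX$barcodes
  for (cm in unique(lib$chrom)) {
    via_pcr <- amplify_chromosome(lib, bc, cm)
    via_meta <- select_subpool(lib, "chromosome", cm)
    expect_identical(via_pcr$full_sequence, via_meta$full_sequence)
  }
  # the chromosome sub-pools partition the library
  sizes <- vapply(unique(lib$chrom), function(cm)
    nrow(select_subpool(lib, "chromosome", cm)), numeric(1))
  expect_equal(sum(sizes), nrow(lib))

  # non-matching primers give an empty pool; empty library passes through
  none <- simulate_pcr(lib, strrep("A", 20), strrep("C", 20))
  expect_equal(nrow(none), 0)
  expect_equal(nrow(simulate_pcr(lib[0, ], "AAAA", "CCCC")), 0)
})

test_that("kb500 sub-pools are interval selections nested in the chromosome", {
  lib <- FX$library
  cm <- lib$chrom[1]
  found <- sort(unique(lib$kb500_index[lib$chrom == cm]))
  all_starts <- c()
  for (ix in found) {
    sub <- select_subpool(lib, "kb500", cm, ix)
    expect_true(all(sub$start >= ix * 5e5 & sub$start < (ix + 1) * 5e5))
    all_starts <- c(all_starts, sub$start)
  }
  expect_setequal(all_starts, lib$start[lib$chrom == cm])
  expect_error(select_subpool(lib, "kb500", cm, 99),
               class = "np_unknown_segment")
  expect_error(select_subpool(lib, "chromosome", "chrZ"),
               class = "np_unknown_segment")
})

test_that("library FASTA round-trips byte-identically", {
  lib <- FX$library
  p1 <- tempfile(fileext = ".fasta")
  write_library_fasta(lib, p1)
  back <- read_library_fasta(p1)
  expect_equal(back$full_sequence, lib$full_sequence)
  expect_equal(back$chrom, lib$chrom)
  expect_equal(back$kb500_index, lib$kb500_index)
  p2 <- tempfile(fileext = ".fasta")
  write_library_fasta(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
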