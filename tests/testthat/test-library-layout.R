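test_that("every-Nth selection within one segment is plain decimation", {
  cand <- data.frame(chrom = "chrA", start = seq(0, 4900, by = 100))
  sel <- subsample(cand, selection_params(step = 5))
  expect_equal(nrow(sel), 10)
  expect_equal(sel$start, seq(0, 4500, by = 500))

  expect_equal(nrow(subsample(cand[0, , drop = FALSE])), 0)
})

test_that("selection restarts per 500 kb segment and matches index enumeration", {
  set.seed(31)
  starts <- sort(c(sample(0:499999, 400), sample(500000:999999, 300)))
  cand <- data.frame(chrom = "chrA", start = starts)
  sel <- subsample(cand, selection_params(step = 5))
  seg <- floor(starts / 5e5)
  want <- unlist(lapply(unique(seg), function(sg) {
    s <- starts[seg == sg]
    s[seq(1, length(s), by = 5)]
  }))
  expect_equal(sel$start, sort(want))
  # membership and strict ordering
  expect_true(all(sel$start %in% cand$start))
  expect_true(all(diff(sel$start) > 0))
})

test_that("selected density tracks candidate density / N within 2%", {
  # uniform synthetic candidate lattice, >= 1000 candidates in one segment
  cand <- data.frame(chrom = "chrA", start = seq(0, by = 350, length.out = 1200))
  sel <- subsample(cand, selection_params(step = 5))
  dens_c <- nrow(cand) / ((max(cand$start) - min(cand$start)) / 1000)
  dens_s <- nrow(sel) / ((max(sel$start) - min(sel$start)) / 1000)
  expect_lt(abs(dens_s - dens_c / 5) / (dens_c / 5), 0.02)
})

test_that("spacing statistics: lattice, explicit gaps, and error path", {
  st <- spacing_stats(seq(0, 900, by = 100))
  expect_equal(st$mean_adjacent, 100)
  expect_equal(st$sd_adjacent, 0)
  expect_equal(st$max_gap, 100)
  expect_equal(st$gaps_over_threshold, 0)

  st <- spacing_stats(c(0, 100, 6000), gap_threshold = 5000)
  expect_equal(st$gaps_over_threshold, 1)
  expect_equal(st$max_gap, 5900)

  expect_error(spacing_stats(c(5)), class = "np_too_few_probes")
  # invariants
  set.seed(32)
  for (i in 1:5) {
    s <- sort(sample(1e6, 50))
    st <- spacing_stats(s)
    expect_gte(st$max_gap, st$mean_adjacent)
    expect_lte(st$gaps_over_threshold, st$n_selected - 1)
  }
})

test_that("endpoint arithmetic reproduces printed per-chromosome values", {
  # chromosome II of the published library: 27,360 probes spanning
  # 163..15,199,262 give an endpoint mean of 555.5 bp (division by n)
  s <- spacing_from_endpoints(163, 15199262, 27360)
  expect_equal(round(s$endpoint_mean, 1), 555.5)
  # chromosome I: 25,174 probes spanning 512..14,999,984 -> 1.68 / kb
  s1 <- spacing_from_endpoints(512, 14999984, 25174)
  expect_equal(round(s1$density_per_kb, 2), 1.68)
  expect_equal(round(s1$endpoint_mean, 1), 595.8)
})

test_that("summary totals use sum-for-counts / unweighted-mean-for-ratios", {
  rows <- data.frame(
    chrom = c("I", "II", "III", "IV", "V", "X"),
    first_coord = c(512, 163, 123, 655, 414, 595),
    last_coord = c(14999984, 15199262, 13599784, 17399857, 20699907, 17599761),
    n_candidates = c(125863, 136793, 133977, 137270, 177948, 161095),
    candidates_per_kb = c(8.39, 9.00, 9.85, 7.89, 8.60, 9.15),
    n_chosen = c(25174, 27360, 22796, 27454, 35590, 32220),
    chosen_per_kb = c(1.68, 1.80, 1.68, 1.58, 1.72, 1.83),
    mean_distance = c(595.8, 555.5, 595.9, 633.8, 581.6, 546.2),
    sd_distance = c(505.9, 484.5, 572.2, 585.4, 460.4, 436.8))
  tab <- summarize_library(rows)
  tot <- tab[tab$chrom == "total", ]
  expect_equal(tot$n_chosen, 170594)
  expect_equal(tot$n_candidates, 872946)
  expect_equal(round(tot$candidates_per_kb, 2), 8.81)
  expect_equal(round(tot$mean_distance, 1), 584.8)

  one <- summarize_library(rows[2, ])
  expect_equal(one$n_chosen[2], one$n_chosen[1])
  expect_equal(one$mean_distance[2], one$mean_distance[1])

  expect_error(summarize_library(rows[, -4]), class = "np_param_error")
})

test_that("summary table round-trips through TSV bit-identically", {
  set.seed(33)
  cand <- data.frame(chrom = rep(c("c1", "c2"), each = 500),
                     start = c(sort(sample(1e6, 500)), sort(sample(1e6, 500))))
  sel <- subsample(cand, selection_params(step = 5))
  tab <- library_summary(cand, sel)
  p <- tempfile(fileext = ".tsv")
  write_summary_tsv(tab, p)
  back <- read_summary_tsv(p)
  expect_equal(back, tab, tolerance = 0)
})

test_that("target-density mode derives a sensible step", {
  cand <- data.frame(chrom = "chrA", start = seq(0, by = 111, length.out = 2000))
  # candidate density ~9/kb; ask for ~1.8/kb -> step 5
  sel <- subsample(cand, selection_params(target_density = 1.8))
  expect_equal(nrow(sel), 400)
  expect_error(selection_params(step = 0), class = "np_param_error")
  expect_error(selection_params(gap_threshold = -1), class = "np_param_error")
})
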