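test_that("fluorophore multiplicity is the configuration product", {
  expect_equal(fluorophore_multiplicity(multiplex_config(2, 2, 2)), 8)
  expect_equal(fluorophore_multiplicity(multiplex_config(1, 1, 1)), 1)
  # (2, 2, 1): enumerate every (bridge, detection, dye-terminus) tuple
  cfg <- multiplex_config(2, 2, 1)
  tuples <- expand.grid(bridge = 1:2, detection = 1:2, terminus = 1:1)
  expect_equal(fluorophore_multiplicity(cfg), nrow(tuples))
  expect_error(multiplex_config(3, 2, 2), class = "np_param_error")
  expect_error(multiplex_config(0, 1, 1), class = "np_param_error")
})

test_that("color capacity counts bounded nonempty channel subsets", {
  expect_equal(color_capacity(3, 2), 6)
  expect_equal(color_capacity(3, 3), 7)
  # (4, 2) verified by powerset enumeration
  subsets <- unlist(lapply(1:2, function(s)
    utils::combn(4, s, simplify = FALSE)), recursive = FALSE)
  expect_equal(color_capacity(4, 2), length(subsets))
})

test_that("color assignment is deterministic: singletons then pairs", {
  ch <- c("A488", "Cy3", "A647")
  sc <- assign_colors(paste0("chr", 1:6), ch, 2)
  codes <- unname(sc$code_per_target)
  expect_equal(codes[[1]], "A488")
  expect_equal(codes[[2]], "Cy3")
  expect_equal(codes[[3]], "A647")
  expect_equal(codes[[4]], c("A488", "Cy3"))
  expect_equal(codes[[5]], c("A488", "A647"))
  expect_equal(codes[[6]], c("Cy3", "A647"))
  # pairwise distinct
  keys <- vapply(codes, paste, "", collapse = "+")
  expect_equal(anyDuplicated(keys), 0L)

  expect_equal(assign_colors("t", ch)$code_per_target[["t"]], "A488")
  err <- tryCatch(assign_colors(paste0("t", 1:7), ch, 2), error = identity)
  expect_s3_class(err, "np_capacity")
  expect_match(conditionMessage(err), "channels")
})

test_that("compiled six-target order sheet has 9 bridges wired correctly", {
  targets <- data.frame(
    target = paste0("chr", 1:6),
    barcode_5p = vapply(1:6, function(i) random_seq(20), ""),
    barcode_3p = vapply(1:6, function(i) random_seq(20), ""),
    stringsAsFactors = FALSE)
  sc <- assign_colors(targets$target, c("A488", "Cy3", "A647"), 2)
  sheet <- compile_hybridization(targets, sc, multiplex_config(), seed = 3)
  bridges <- sheet[sheet$role == "bridge", ]
  detections <- sheet[sheet$role == "detection", ]
  # 3 singleton codes + 3 pair codes -> 3 + 6 = 9 bridge species
  expect_equal(nrow(bridges), 9)
  expect_equal(anyDuplicated(bridges$species), 0L)
  # every bridge 5' segment is the reverse complement of a target barcode
  all_bc <- c(targets$barcode_5p, targets$barcode_3p)
  for (i in seq_len(nrow(bridges))) {
    head20 <- substr(bridges$sequence[i], 1, 20)
    expect_true(rc1(head20) %in% all_bc)
    # tandem docks: remainder is two copies of the dye's dock
    rest <- substring(bridges$sequence[i], 21)
    expect_equal(substr(rest, 1, 20), substr(rest, 21, 40))
    # detection oligo for the dye is the dock's reverse complement
    det <- detections$sequence[detections$dye == bridges$dye[i]]
    expect_equal(det, rc1(substr(rest, 1, 20)))
  }
  # pair-coded targets route their two dyes via distinct barcodes (5'+3')
  for (tg in targets$target) {
    tb <- bridges[bridges$target == tg, ]
    if (nrow(tb) == 2) {
      heads <- substr(tb$sequence, 1, 20)
      expect_equal(rc1(heads[1]),
                   targets$barcode_5p[targets$target == tg])
      expect_equal(rc1(heads[2]),
                   targets$barcode_3p[targets$target == tg])
    }
  }
  # no dock shared between two dyes
  expect_equal(anyDuplicated(unique(sheet[, c("dye", "dock_id")])$dock_id), 0L)
})

test_that("addressability: each (target, dye) has exactly one bridge chain", {
  targets <- data.frame(target = c("a", "b"),
                        barcode_5p = c(random_seq(20), random_seq(20)),
                        barcode_3p = c(random_seq(20), NA),
                        stringsAsFactors = FALSE)
  sc <- assign_colors(targets$target, c("g", "r"), max_code_size = 2)
  # a -> {g}, b -> {r}; single-channel codes need only the 5' barcode
  sheet <- compile_hybridization(targets, sc)
  expect_equal(nrow(sheet[sheet$role == "bridge", ]), 2)
  for (tg in targets$target) {
    dyes <- unlist(sc$code_per_target[[tg]])
    for (d in dyes)
      expect_equal(sum(sheet$role == "bridge" & sheet$target == tg &
                         sheet$dye == d), 1)
  }
  # a pair code on a target with only one addressable barcode errors
  sc2 <- list(channels = c("g", "r"),
              code_per_target = list(a = c("g", "r"), b = "r"))
  class(sc2) <- "ColorScheme"
  targets2 <- targets
  targets2$barcode_3p <- NA
  expect_error(compile_hybridization(targets2, sc2),
               class = "np_unaddressable")
})

test_that("order sheet and scheme serialize", {
  targets <- data.frame(target = "t", barcode_5p = random_seq(20),
                        barcode_3p = NA, stringsAsFactors = FALSE)
  sc <- assign_colors("t", c("g", "r"))
  sheet <- compile_hybridization(targets, sc)
  p <- tempfile(fileext = ".tsv")
  write_order_sheet(sheet, p)
  back <- read.delim(p)
  expect_equal(nrow(back), nrow(sheet))
  pj <- tempfile(fileext = ".json")
  write_color_scheme(sc, pj)
  parsed <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(parsed$channels, c("g", "r"))
})
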