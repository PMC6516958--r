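test_that("two-valued stacks threshold exactly between the modes", {
  st <- array(10, c(4, 8, 8))
  st[2:3, 3:5, 3:5] <- 200
  mask <- threshold_stack(st)
  expect_identical(mask, st > 10)
  # idempotence on binary input
  expect_identical(threshold_stack(mask * 1L), mask * 1L > 0)
  expect_error(threshold_stack(array(7, c(2, 2, 2))),
               class = "np_degenerate_histogram")
})

test_that("isodata threshold matches the literal intermeans loop", {
  set.seed(51)
  for (i in 1:50) {
    v <- c(rpois(400, lambda = runif(1, 5, 30)),
           rpois(100, lambda = runif(1, 80, 300)))
    st <- array(v, c(5, 10, 10))
    expect_equal(threshold_stack(st, return_mask = FALSE),
                 oracle_isodata(v))
  }
})

test_that("size filter is strict and labeling matches flood fill", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:5, 2:5, 2:5] <- TRUE          # 64 voxels
  lab <- extract_objects(m, quant_params())
  expect_equal(max(lab), 1)
  expect_equal(attr(lab, "sizes"), 64L)

  m2 <- array(FALSE, c(10, 10, 10))
  m2[2:4, 2:4, 2:4] <- TRUE          # 27 voxels <= 30 -> dropped
  lab2 <- extract_objects(m2, quant_params())
  expect_equal(max(lab2), 0)
  lab2b <- extract_objects(m2, quant_params(min_object_voxels = 26))
  expect_equal(max(lab2b), 1)
})

test_that("corner-touching cubes: 1 object under 26-, 2 under 6-connectivity", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[5:7, 5:7, 5:7] <- TRUE   # touches only at the (4,4,4)/(5,5,5) corner
  lab26 <- extract_objects(m, quant_params(min_object_voxels = 0,
                                           connectivity = 26))
  lab6 <- extract_objects(m, quant_params(min_object_voxels = 0,
                                          connectivity = 6))
  expect_equal(max(lab26), 1)
  expect_equal(max(lab6), 2)
  expect_equal(sort(attr(lab26, "sizes")), oracle_component_sizes(m, 26))
  expect_equal(sort(attr(lab6, "sizes")), oracle_component_sizes(m, 6))
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(52)
  for (i in 1:6) {
    m <- array(runif(8 * 9 * 10) < 0.25, c(8, 9, 10))
    for (conn in c(6, 26)) {
      lab <- extract_objects(m, quant_params(min_object_voxels = 0,
                                             connectivity = conn))
      expect_equal(sort(attr(lab, "sizes")), oracle_component_sizes(m, conn))
    }
  }
})

test_that("territory measurement: disjoint, identical, and ellipsoid cases", {
  a <- array(10, c(16, 24, 24)); a[4:8, 4:10, 4:10] <- 200
  b <- array(10, c(16, 24, 24)); b[10:14, 14:20, 14:20] <- 200
  st <- measure_territories(list(A = a, B = b))
  expect_equal(unname(st$overlap["A", "B"]), 0)
  expect_equal(unname(st$overlap["A", "A"]), unname(st$volume["A"]))

  st2 <- measure_territories(list(A = a, B = a))
  expect_equal(unname(st2$overlap["A", "B"]), unname(st2$volume["A"]))
  expect_equal(unname(st2$overlap_fraction["A", "B"]), 1)

  # noiseless voxelized ellipsoid: volume within 5% of (4/3) pi abc
  img <- array(10, c(32, 40, 48))
  ell <- nemapaint:::ellipsoid_mask(c(32, 40, 48), c(16, 20, 24), c(8, 10, 12))
  img[ell] <- 200
  stats <- measure_territories(list(ch1 = img))
  analytic <- 4 / 3 * pi * 8 * 10 * 12
  expect_lt(abs(stats$volume[["ch1"]] - analytic) / analytic, 0.05)

  expect_error(measure_territories(list(a, array(0:1, c(2, 2, 2)))),
               class = "np_dim_mismatch")
})

test_that("volume invariants: union bound and size-filter monotonicity", {
  set.seed(54)
  sim <- simulate_nucleus_image(sim_nucleus_params(
    n_territories = 2, blur_sigma = 0.8, noise = TRUE, seed = 55))
  st <- measure_territories(sim$stacks)
  un <- sum(st$masks[[1]] | st$masks[[2]])
  expect_lte(un, st$volume[[1]] + st$volume[[2]])
  if (st$overlap[1, 2] == 0)
    expect_equal(un, st$volume[[1]] + st$volume[[2]])
  # raising the size filter never increases measured volume
  v_lo <- measure_territories(sim$stacks, quant_params(min_object_voxels = 0))
  v_hi <- measure_territories(sim$stacks,
                              quant_params(min_object_voxels = 100))
  expect_true(all(v_hi$volume <= v_lo$volume))
  # symmetric overlap bounded by the smaller volume
  expect_equal(st$overlap, t(st$overlap))
  expect_lte(st$overlap[1, 2], min(st$volume))
})

test_that("volumes and overlaps recover ground truth across seeds 1-10", {
  for (seed in 1:10) {
    sim <- simulate_nucleus_image(sim_nucleus_params(
      dims = c(28, 56, 56), n_territories = 2, semiaxis_range = c(5, 9),
      placement = "overlapping", target_overlap = 0.25,
      blur_sigma = 1, noise = FALSE, seed = seed))
    st <- measure_territories(sim$stacks)
    for (ch in names(sim$stacks)) {
      rel <- abs(st$volume[[ch]] - sim$truth$volume[[ch]]) /
        sim$truth$volume[[ch]]
      expect_lt(rel, 0.10)
    }
    tr_ov <- sim$truth$overlap[1, 2]
    if (tr_ov > 0) {
      expect_lt(abs(st$overlap[1, 2] - tr_ov) / tr_ov, 0.15)
    }
  }
})

test_that("inflating territory radii ~15% raises measured volume >= 40%", {
  # the in-silico analogue of territory decondensation: same nuclei, same
  # pipeline, semi-axes scaled by 1.15 (1.15^3 = 1.52x true volume)
  young <- simulate_nucleus_image(sim_nucleus_params(
    dims = c(28, 56, 56), n_territories = 1, semiaxis_range = c(7, 7),
    blur_sigma = 1, noise = TRUE, seed = 56))
  aged <- simulate_nucleus_image(sim_nucleus_params(
    dims = c(28, 56, 56), n_territories = 1,
    semiaxis_range = c(7 * 1.15, 7 * 1.15), blur_sigma = 1, noise = TRUE,
    seed = 56))
  vy <- measure_territories(young$stacks)$volume[[1]]
  va <- measure_territories(aged$stacks)$volume[[1]]
  expect_gte((va - vy) / vy, 0.40)
})

test_that("territory CSV report matches the stats object", {
  sim <- simulate_nucleus_image(sim_nucleus_params(n_territories = 2,
                                                   seed = 57))
  st <- measure_territories(sim$stacks, voxel_size = c(0.2, 0.1, 0.1))
  p <- tempfile(fileext = ".csv")
  write_territory_csv(st, p)
  back <- read.csv(p)
  expect_equal(back$volume_voxels, unname(st$volume))
  expect_equal(back$volume_um3, unname(st$volume) * 0.002)
  expect_equal(back$overlap_ch2[1], st$overlap["ch1", "ch2"][[1]])
})
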