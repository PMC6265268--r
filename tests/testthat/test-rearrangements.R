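# small genome-wide balanced matrix with a controllable row
scan_fixture <- function(n = 300, bg = 0.001) {
  bins <- make_bins(c(chrA = n * 50e3), 50e3)
  set.seed(41)
  mat <- matrix(abs(rnorm(n * n, bg, bg / 10)), n)
  mat <- (mat + t(mat)) / 2
  m <- contact_matrix(mat, bins, state = "raw")
  m$state <- "balanced"
  m$bias <- rep(1, n)
  m
}

test_that("v4c_profile returns the matrix row with masked bins undefined", {
  m <- decay_matrix(3, function(d) 10 - d, c(chrA = 150e3))
  expect_equal(v4c_profile(m, 2), m$mat[2, ])
  expect_equal(v4c_profile(m, 1)[3], v4c_profile(m, 3)[1])
  m$bins <- data.table::copy(m$bins); m$bins$mappable[3] <- FALSE
  expect_true(is.na(v4c_profile(m, 1)[3]))
  expect_error(v4c_profile(m, 3), "masked")
})

test_that("peak thresholds follow the stated inequalities", {
  m <- scan_fixture()
  i <- 60
  m$mat[i, i] <- 100
  m$mat[i, 260] <- m$mat[260, i] <- 20    # distance 200 bins, above 0.15*v_i
  pk <- v4c_peak_scan(m)
  hit <- pk[pk$viewpoint == i]
  expect_true(260 %in% hit$target)

  # same height at distance 40 bins -> inside the exclusion zone
  m2 <- scan_fixture()
  m2$mat[i, i] <- 100
  m2$mat[i, i + 40] <- m2$mat[i + 40, i] <- 20
  pk2 <- v4c_peak_scan(m2)
  expect_false((i + 40) %in% pk2[pk2$viewpoint == i]$target)

  # below the height fraction: 0.15 * 100 = 15 > 12
  m3 <- scan_fixture()
  m3$mat[i, i] <- 100
  m3$mat[i, 260] <- m3$mat[260, i] <- 12
  pk3 <- v4c_peak_scan(m3)
  expect_false(260 %in% pk3$target[pk3$viewpoint == i])
})

test_that("uniform profiles produce no peaks", {
  n <- 120
  bins <- make_bins(c(chrA = n * 50e3), 50e3)
  m <- contact_matrix(matrix(1, n, n), bins, state = "raw")
  m$state <- "balanced"; m$bias <- rep(1, n)
  expect_equal(nrow(v4c_peak_scan(m)), 0L)
})

test_that("viewpoints near unmappable bins are skipped", {
  m <- scan_fixture()
  m$mat[60, 60] <- 100
  m$mat[60, 260] <- m$mat[260, 60] <- 20
  m$bins <- data.table::copy(m$bins)
  m$bins$mappable[55] <- FALSE           # within +/-7 of viewpoint 60
  pk <- v4c_peak_scan(m)
  expect_false(60 %in% pk$viewpoint)
})

test_that("peak calling is monotone in both thresholds", {
  m <- scan_fixture()
  set.seed(42)
  hot <- sample(60:240, 6)
  for (h in hot) { m$mat[h, h] <- 50; m$mat[h, 280] <- m$mat[280, h] <- 10 }
  strict <- v4c_peak_scan(m, height_fraction = 0.15, percentile = 99.5)
  loose_h <- v4c_peak_scan(m, height_fraction = 0.05, percentile = 99.5)
  loose_p <- v4c_peak_scan(m, height_fraction = 0.15, percentile = 98)
  key <- function(p) paste(p$viewpoint, p$target)
  expect_true(all(key(strict) %in% key(loose_h)))
  expect_true(all(key(strict) %in% key(loose_p)))
})

test_that("compare_scans keeps case-only peaks and merges adjacent runs", {
  pk <- function(vp, tg) data.table::data.table(viewpoint = vp, target = tg,
    v_i = 1, v_j = seq_along(vp), quantile_cut = 0)
  expect_equal(nrow(compare_scans(pk(10, 200), pk(10, 200))), 0L)
  expect_equal(nrow(compare_scans(pk(10, 200), pk(11, 201))), 0L)  # within tolerance
  expect_equal(nrow(compare_scans(pk(10, 200), pk(14, 200))), 1L)  # 4 > tolerance
  # adjacent case peaks merge into one call with the strongest as breakpoint
  calls <- compare_scans(pk(c(10, 11, 12), c(200, 201, 202)),
                         pk(integer(0), integer(0)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$viewpoint_from, 10L)
  expect_equal(calls$viewpoint_to, 12L)
  expect_equal(calls$bp_viewpoint, 12L)   # v_j increasing, max at last
})

test_that("boundary merging collapses near-duplicates", {
  expect_equal(merge_boundaries(c(10L, 30L), c(10L, 31L, 50L)), c(10L, 30L, 50L))
  expect_equal(merge_boundaries(integer(0), 5L), 5L)
})

test_that("TAD intensity difference is zero on identical samples", {
  m <- decay_matrix(40, function(d) 1 / (d + 1), c(chrA = 2e6))
  bset <- data.table::data.table(chrom = "chrA", start = 0, end = 0,
                                 bin = c(10L, 25L), strength = 1)
  td <- tad_intensity_difference(m, m, bset, bset)
  expect_equal(nrow(td), 1L)
  expect_equal(td$difference, 0)
  expect_equal(td$from_bin, 10L)
  expect_equal(td$to_bin, 25L)
})

test_that("a planted case-specific domain shows a positive difference", {
  n <- 60
  base <- decay_matrix(n, function(d) 1 / (d + 1), c(chrA = 3e6))
  case <- base
  case$mat <- base$mat
  case$mat[21:34, 21:34] <- case$mat[21:34, 21:34] * 3
  bset <- data.table::data.table(chrom = "chrA", start = 0, end = 0,
                                 bin = c(10L, 20L, 35L, 50L), strength = 1)
  td <- tad_intensity_difference(case, base, bset, bset)
  expect_equal(td$difference[1], 0)
  expect_gt(td$difference[2], 0)
  expect_equal(td$difference[3], 0)
})
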