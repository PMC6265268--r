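test_that("bin_pairs counts pairs and conserves mass", {
  bins <- make_bins(c(c1 = 150e3, c2 = 100e3), 50e3)
  p <- data.table::data.table(read_id = as.character(1:5),
    chrom1 = c("c1", "c1", "c1", "c1", "c2"),
    pos1 = c(10, 20, 30, 110e3, 60e3),
    strand1 = "+",
    chrom2 = c("c1", "c1", "c1", "c1", "c2"),
    pos2 = c(60e3, 70e3, 80e3, 120e3, 99e3),
    strand2 = "-")
  m <- bin_pairs(p, bins)
  expect_equal(m$mat[1, 2], 3)           # three pairs in (bin 1, bin 2)
  expect_equal(m$mat[2, 1], 3)
  expect_equal(m$mat[3, 3], 1)           # both loci in bin 3: diagonal
  expect_equal(m$mat[5, 5], 1)
  expect_equal(sum(m$mat[upper.tri(m$mat, diag = TRUE)]), nrow(p))
})

test_that("bin_pairs marginals equal independent per-bin locus counts", {
  set.seed(5)
  bins <- make_bins(c(c1 = 500e3, c2 = 300e3), 50e3)
  n <- 200
  p <- data.table::data.table(read_id = as.character(seq_len(n)),
    chrom1 = sample(c("c1", "c2"), n, TRUE), pos1 = NA_real_, strand1 = "+",
    chrom2 = sample(c("c1", "c2"), n, TRUE), pos2 = NA_real_, strand2 = "+")
  p$pos1 <- round(runif(n, 0, ifelse(p$chrom1 == "c1", 499e3, 299e3)))
  p$pos2 <- round(runif(n, 0, ifelse(p$chrom2 == "c1", 499e3, 299e3)))
  m <- bin_pairs(p, bins)
  # recount loci independently (diagonal pairs contribute two loci but the
  # symmetric matrix stores them once, so count column sums with diagonal
  # doubled)
  loc_bins <- c(lowhic:::locate_bins(bins, p$chrom1, p$pos1),
                lowhic:::locate_bins(bins, p$chrom2, p$pos2))
  want <- tabulate(loc_bins, nbins = nrow(bins))
  expect_equal(unname(colSums(m$mat) + diag(m$mat)), want)
})

test_that("low-coverage masking uses the fractional median rule", {
  bins <- make_bins(c(c1 = 200e3), 50e3)
  mk <- function(cov) {
    mat <- diag(cov)   # coverage = row sums
    contact_matrix(mat, bins, state = "raw")
  }
  mm <- mask_low_coverage(mk(c(100, 100, 100, 5)))
  expect_equal(mm$bins$mappable, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mm$mat[4, ] == 0))
  expect_true(all(mask_low_coverage(mk(rep(7, 4)))$bins$mappable))
  expect_equal(mask_low_coverage(mk(c(10, 10, 10, 0)))$bins$mappable[4], FALSE)
  expect_error(mask_low_coverage(mk(rep(0, 4))), "empty")
})

test_that("KR balancing solves the 2x2 closed form", {
  bins <- make_bins(c(c1 = 100e3), 50e3)
  m <- contact_matrix(matrix(c(4, 2, 2, 1), 2), bins)
  mb <- kr_balance(m)
  expect_equal(mb$bias, c(2^-1.5, 2^-0.5), tolerance = 1e-6)
  expect_equal(unname(rowSums(mb$mat)), c(1, 1), tolerance = 1e-6)
  expect_equal(mb$state, "balanced")
})

test_that("KR balancing leaves equal-row-sum matrices uniform", {
  bins <- make_bins(c(c1 = 200e3), 50e3)
  mat <- matrix(1, 4, 4)
  mb <- kr_balance(contact_matrix(mat, bins))
  expect_equal(mb$bias, rep(0.5, 4), tolerance = 1e-6)
})

test_that("KR agrees with the Sinkhorn oracle on random matrices", {
  set.seed(12)
  bins <- make_bins(c(c1 = 20 * 50e3), 50e3)
  for (rep in 1:5) {
    A <- matrix(runif(400, 0.2, 2), 20)
    A <- (A + t(A)) / 2
    mb <- kr_balance(contact_matrix(A, bins))
    x <- oracle_sinkhorn(A)
    expect_lt(max(abs(mb$bias / x - 1)), 1e-4)
    expect_lt(max(abs(rowSums(mb$mat) - 1)), 1e-6)
  }
})

test_that("per-chromosome balancing zeroes trans and balances each block", {
  set.seed(13)
  bins <- make_bins(c(c1 = 250e3, c2 = 250e3), 50e3)
  A <- matrix(runif(100, 0.5, 2), 10); A <- (A + t(A)) / 2
  mb <- kr_balance(contact_matrix(A, bins), per_chromosome = TRUE)
  expect_true(all(mb$mat[1:5, 6:10] == 0))
  expect_equal(unname(rowSums(mb$mat[1:5, 1:5])), rep(1, 5), tolerance = 1e-6)
})

test_that("expected-by-distance averages mappable diagonals", {
  bins <- make_bins(c(c1 = 150e3), 50e3)
  mat <- matrix(0, 3, 3); mat[1, 2] <- 2; mat[2, 3] <- 4
  mat <- mat + t(mat); diag(mat) <- 1
  m <- contact_matrix(mat, bins); m$state <- "balanced"; m$bias <- rep(1, 3)
  e <- expected_by_distance(m)
  expect_equal(e$expected, c(1, 3, 0))
  expect_equal(e$n_possible, c(3, 2, 1))

  # constant diagonals are returned exactly
  md <- decay_matrix(8, function(d) 10 - d, c(chrA = 400e3))
  ed <- expected_by_distance(md)
  expect_equal(ed$expected, 10 - ed$d)

  # masked bin excluded from numerator and denominator
  m2 <- m
  m2$bins <- data.table::copy(bins); m2$bins$mappable[2] <- FALSE
  e2 <- expected_by_distance(m2)
  expect_equal(e2$n_possible, c(2, 0, 1))   # every d=1 pair touches bin 2
  expect_true(is.na(e2$expected[2]))
})

test_that("O/E transform removes decay and propagates masks", {
  m <- decay_matrix(10, function(d) 2^(-d), c(chrA = 500e3))
  oe <- oe_transform(m)
  expect_equal(oe$state, "oe")
  expect_true(all(abs(oe$mat[is.finite(oe$mat)] - 1) < 1e-12))

  # c * e(d) construction returns c everywhere
  m2 <- m; m2$mat <- m$mat * 3.5
  e <- expected_by_distance(m)
  oe2 <- oe_transform(m2, e)
  expect_true(all(abs(oe2$mat[is.finite(oe2$mat)] - 3.5) < 1e-12))

  # masked bins stay undefined
  m3 <- m; m3$bins <- data.table::copy(m$bins); m3$bins$mappable[4] <- FALSE
  oe3 <- oe_transform(m3)
  expect_true(all(is.na(oe3$mat[4, ])))
})

test_that("difference matrix applies the no-signal rule both ways", {
  m <- decay_matrix(6, function(d) 1 / (d + 1), c(chrA = 300e3))
  d0 <- difference_matrix(m, m)
  expect_true(all(d0[is.finite(d0)] == 0))

  a <- m; b <- m
  a$mat[2, 5] <- a$mat[5, 2] <- 0
  b$mat[2, 5] <- b$mat[5, 2] <- 0   # zero in both -> masked
  b$mat[1, 4] <- b$mat[4, 1] <- 0   # zero in one -> kept under "both"
  d <- difference_matrix(a, b)
  expect_true(is.na(d[2, 5]))
  expect_false(is.na(d[1, 4]))
  d2 <- difference_matrix(a, b, no_signal = "either")
  expect_true(is.na(d2[1, 4]))

  expect_error(difference_matrix(m, decay_matrix(5, function(d) 1,
    c(chrA = 250e3))), "differ")
})

test_that("distance-stratified correlation behaves on self and anti pairs", {
  m <- decay_matrix(20, function(d) 1 / (d + 1), c(chrA = 1e6))
  cc <- distance_stratified_correlation(m, m, stratum_width = 250e3)
  # self-correlation is 1 in every defined stratum
  expect_true(all(abs(cc$r[!is.na(cc$r)] - 1) < 1e-12))
  # strata of 250 kb at 50 kb bins hold 5 diagonals each
  expect_equal(cc$stratum_end - cc$stratum_start, rep(250e3, nrow(cc)))
  expect_equal(cc$n[1], sum(20:16))

  # perfect anti-correlation within strata
  set.seed(3)
  a <- m
  noise <- matrix(runif(400), 20); noise <- (noise + t(noise)) / 2
  a$mat <- noise
  b <- a; b$mat <- -a$mat + 10
  cb <- distance_stratified_correlation(a, b, stratum_width = 250e3)
  expect_true(all(abs(cb$r[!is.na(cb$r)] + 1) < 1e-12))
})
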