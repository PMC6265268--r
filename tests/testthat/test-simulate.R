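test_that("the simulator is deterministic under a fixed seed", {
  spec <- map_spec(chrom_lengths = c(chrA = 5e6, chrB = 5e6), depth = 2e5,
                   seed = 33)
  a <- simulate_contact_map(spec)
  b <- simulate_contact_map(spec)
  expect_identical(a$matrix$mat, b$matrix$mat)
  expect_error(map_spec(depth = 2e6), "seed")
  expect_error(map_spec(depth = 0, seed = 1), "positive")
})

test_that("mass, symmetry and masking contracts hold", {
  spec0 <- map_spec(chrom_lengths = c(chrA = 5e6, chrB = 5e6), depth = 2e5,
                    seed = 34)
  m0 <- simulate_contact_map(spec0)$matrix$mat
  expect_equal(m0, t(m0))
  mass <- sum(m0[upper.tri(m0, diag = TRUE)])
  expect_lt(abs(mass - 2e5) / 2e5, 0.05)   # Poisson fluctuation around depth

  spec <- map_spec(chrom_lengths = c(chrA = 5e6, chrB = 5e6), depth = 2e5,
                   masked_fraction = 0.05, seed = 34)
  sim <- simulate_contact_map(spec)
  expect_equal(length(sim$truth$masked_bins), 10L)  # 5% of 200 bins
  expect_true(all(sim$matrix$mat[sim$truth$masked_bins, ] == 0))
})

test_that("decay exponent is recovered from the expected profile", {
  spec <- map_spec(chrom_lengths = c(chrA = 20e6, chrB = 20e6), depth = 2e6,
                   alpha = 1, seed = 35)
  mb <- kr_balance(mask_low_coverage(simulate_contact_map(spec)$matrix))
  slope <- fit_decay_exponent(expected_by_distance(mb))
  expect_lt(abs(slope + 1), 0.1)
})

test_that("translocation injection anchors cis-like decay at the breakpoints", {
  spec <- map_spec(depth = 2e6, seed = 36)
  sim <- simulate_contact_map(spec)
  tr <- inject_translocation(sim,
    rearrangement_spec("chrA", "chrB", 12e6, 5e6), seed = 2)
  blk <- tr$matrix$mat[1:400, 401:800]
  # maximal inter-chromosomal signal at the breakpoint-pair bin
  peak <- which(blk == max(blk), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[["row"]] - tr$truth$bpA_bin), 1)
  expect_lte(abs(peak[["col"]] - (tr$truth$bpB_bin - 400)), 1)
  # decay away from the breakpoint along the fused axis
  expect_gt(blk[241, 101], mean(blk))
  expect_gt(blk[241, 101], blk[241, 60])

  # non-reciprocal fusion fills only the der(A) quadrant
  tr1 <- inject_translocation(sim,
    rearrangement_spec("chrA", "chrB", 12e6, 5e6, reciprocal = FALSE), seed = 2)
  blk1 <- tr1$matrix$mat[1:400, 401:800] - sim$matrix$mat[1:400, 401:800]
  expect_gt(sum(blk1[1:241, 101:400]), 0)
  expect_equal(sum(blk1[242:400, 1:100]), 0)

  # zero intensity leaves the matrix untouched
  tr0 <- inject_translocation(sim,
    rearrangement_spec("chrA", "chrB", 12e6, 5e6, intensity = 0), seed = 2)
  expect_identical(tr0$matrix$mat, sim$matrix$mat)
  expect_error(inject_translocation(sim,
    rearrangement_spec("chrA", "chrB", 30e6, 5e6), seed = 2), "breakpoint")
})

test_that("planted artefact fractions are recovered by the pair filters", {
  g <- random_genome(c(chrA = 1e6, chrB = 1e6), seed = 44)
  fm <- digest_genome(g, "mboi")
  spec <- pair_sim_spec(fm, n = 2e4, frac_duplicate = 0.1,
                        frac_self_ligation = 0.05, frac_unligated = 0.05,
                        seed = 45)
  sim <- simulate_read_pairs(spec)
  res <- process_pairs(sim$reads, fm)
  n <- res$stats$n_pairs
  f <- res$stats$filtered
  sigma <- function(p) 3 * sqrt(p * (1 - p) / n)
  # outward/inward planted fractions plus the share of duplicates copied
  # from them land within binomial error of the planted rates
  expect_lt(abs(f$inward_short / n - 0.055), sigma(0.055) + 0.01)
  expect_lt(abs(f$outward_short / n - 0.055), sigma(0.055) + 0.01)
  expect_gt(f$duplicate / n, 0.07)
  # labels agree with the flags for planted artefacts; the rare exceptions
  # are short pairs that happen to fall on one long fragment, where the
  # same_fragment flag takes precedence
  pl <- merge(res$pairs, sim$truth, by = "read_id")
  self_f <- pl$filter[pl$label == "self_ligation"]
  unlig_f <- pl$filter[pl$label == "unligated"]
  expect_gt(mean(self_f == "outward_short"), 0.95)
  expect_true(all(self_f %in% c("outward_short", "same_fragment")))
  expect_gt(mean(unlig_f == "inward_short"), 0.95)
  expect_true(all(unlig_f %in% c("inward_short", "same_fragment")))
})

test_that("a clean library produces only chance-level flags", {
  g <- random_genome(c(chrA = 1e6), seed = 46)
  fm <- digest_genome(g, "mboi")
  spec <- pair_sim_spec(fm, n = 5e3, frac_trans = 0, seed = 47)
  res <- process_pairs(simulate_read_pairs(spec)$reads, fm)
  f <- res$stats$filtered
  expect_equal(f$inward_short + f$outward_short + f$duplicate, 0L)
  expect_lt(f$same_fragment / 5e3, 0.01)
  expect_error(pair_sim_spec(fm, 100, frac_duplicate = 0.9,
                             frac_same_fragment = 0.2, seed = 1), "sum")
})

test_that("compartment labels alternate with the stated block size", {
  bins <- make_bins(c(chrA = 2e6), 50e3)
  lab <- checkerboard_labels(bins, block_bins = 10L)
  expect_equal(lab[1:10], rep("A", 10))
  expect_equal(lab[11:20], rep("B", 10))
  expect_equal(rle(lab)$lengths, rep(10L, 4))
})
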