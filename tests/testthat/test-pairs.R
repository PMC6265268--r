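test_that("ligation junction scanning splits reads at the junction midpoint", {
  expect_equal(scan_ligation_junctions("AAAAGATCGATCTTTT"),
               c("AAAAGATC", "GATCTTTT"))
  expect_equal(scan_ligation_junctions("ACGTACGT"), "ACGTACGT")
  # two junctions -> three sub-reads, each keeping its half-site
  expect_equal(scan_ligation_junctions("TTTTGATCGATCAAAATTTTGATCGATCCCCC"),
               c("TTTTGATC", "GATCAAAATTTTGATC", "GATCCCCC"))
  expect_equal(scan_ligation_junctions(""), character(0))
  expect_error(scan_ligation_junctions("ACGT", junction = ""), "non-empty")
})

test_that("mapq filter is strict at the threshold", {
  reads <- aligned_reads(c("a", "b", "c"), "c1", c(10, 20, 30), "+", c(3L, 2L, 0L))
  mq <- mapq_filter(reads, 3L)
  expect_equal(mq$reads$read_id, "a")
  expect_equal(mq$n_discarded, 2L)
})

test_that("read-group classification follows the 2/3/4+ read rules", {
  co <- c("chr1", "chr2")
  # case i: plain mate pair
  r <- aligned_reads(c("p", "p"), c("chr1", "chr2"), c(1000, 5000),
                     c("+", "-"), 60L)
  cl <- classify_read_groups(r, co)
  expect_equal(cl$pairs$classification, "case_i")
  expect_equal(cl$pairs$pos1, 1000)
  expect_equal(cl$pairs$pos2, 5000)

  # case ii: two of three reads within 100 bp -> merged locus is the
  # 5'-most record
  r3 <- aligned_reads(rep("q", 3), c("chr1", "chr1", "chr2"),
                      c(1050, 1000, 5000), c("+", "+", "-"), 60L)
  cl3 <- classify_read_groups(r3, co)
  expect_equal(cl3$pairs$classification, "case_ii")
  expect_equal(cl3$pairs$chrom1, "chr1")
  expect_equal(cl3$pairs$pos1, 1000)
  expect_equal(cl3$pairs$pos2, 5000)

  # case ii without co-location -> discarded
  r3b <- aligned_reads(rep("r", 3), c("chr1", "chr1", "chr2"),
                       c(1000, 2000, 5000), "+", 60L)
  clb <- classify_read_groups(r3b, co)
  expect_equal(nrow(clb$pairs), 0L)
  expect_equal(clb$n_discarded[["case_ii_discarded"]], 1L)

  # 4+ reads and singletons are discarded
  r4 <- aligned_reads(c(rep("s", 4), "t"), "chr1",
                      c(1, 200, 400, 600, 800), "+", 60L)
  cl4 <- classify_read_groups(r4, co)
  expect_equal(nrow(cl4$pairs), 0L)
  expect_equal(cl4$n_discarded[["case_iii_discarded"]], 1L)
  expect_equal(cl4$n_discarded[["unpaired"]], 1L)
})

test_that("pairs are canonicalised to upper-triangle order", {
  co <- c("chr1", "chr2")
  r <- aligned_reads(c("p", "p", "q", "q"),
                     c("chr2", "chr1", "chr1", "chr1"),
                     c(5000, 1000, 900, 100), c("-", "+", "+", "-"), 60L)
  cl <- classify_read_groups(r, co)
  expect_true(all(cl$pairs$chrom1 == "chr1"))
  expect_equal(cl$pairs[cl$pairs$read_id == "q"]$pos1, 100)
  expect_equal(cl$pairs[cl$pairs$read_id == "q"]$strand1, "-")
})

test_that("fragment assignment finds the containing fragment and site distance", {
  fm <- digest_genome(c(f1 = paste0(strrep("A", 2999), "GATC",
                                    strrep("T", 5997))), "mboi")
  # fragments [0,2999), [2999,9000)
  p <- data.table::data.table(read_id = "x", chrom1 = "f1", pos1 = 3100,
    strand1 = "+", chrom2 = "f1", pos2 = 2999, strand2 = "-")
  p <- assign_fragments(p, fm)
  expect_equal(p$frag1, 2)
  expect_equal(p$sitedist1, 101)   # 3100 - 2999
  expect_equal(p$frag2, 2)         # half-open: start belongs to the fragment
  expect_equal(p$sitedist2, 0)
  # midpoint symmetry
  pm <- data.table::data.table(read_id = "y", chrom1 = "f1", pos1 = 1499.5,
    strand1 = "+", chrom2 = "f1", pos2 = 5999.5, strand2 = "+")
  pm <- assign_fragments(pm, fm)
  expect_equal(pm$sitedist1, 2999 / 2)
  expect_error(assign_fragments(data.table::data.table(read_id = "z",
    chrom1 = "nope", pos1 = 1, strand1 = "+", chrom2 = "f1", pos2 = 1,
    strand2 = "+"), fm), "unknown chromosome")
})

test_that("bias filters fire exactly per definition", {
  mk <- function(pos1, pos2, s1, s2, f1 = 1, f2 = 2, sd1 = 10, sd2 = 10,
                 c1 = "c", c2 = "c")
    data.table::data.table(read_id = "r", chrom1 = c1, pos1 = pos1,
      strand1 = s1, chrom2 = c2, pos2 = pos2, strand2 = s2, frag1 = f1,
      frag2 = f2, sitedist1 = sd1, sitedist2 = sd2)
  # same fragment
  expect_true(filter_pairs(mk(100, 5e5, "+", "+", f1 = 3, f2 = 3))$same_fragment)
  # inward at 8 kb flagged, 12 kb not
  expect_true(filter_pairs(mk(1e5, 1e5 + 8e3, "+", "-"))$inward_short)
  expect_false(filter_pairs(mk(1e5, 1e5 + 12e3, "+", "-"))$inward_short)
  # outward at 8 kb
  expect_true(filter_pairs(mk(1e5, 1e5 + 8e3, "-", "+"))$outward_short)
  # same orientation never orientation-flagged
  p <- filter_pairs(mk(1e5, 1e5 + 3e3, "+", "+"))
  expect_false(p$inward_short || p$outward_short)
  # trans pairs never orientation-flagged
  pt <- filter_pairs(mk(1e5, 1e5 + 3e3, "+", "-", c2 = "d"))
  expect_false(pt$inward_short || pt$outward_short)
  # site distance strictly > 5 kb
  expect_true(filter_pairs(mk(1e5, 5e5, "+", "+", sd1 = 6e3))$far_from_site)
  expect_false(filter_pairs(mk(1e5, 5e5, "+", "+", sd1 = 5e3))$far_from_site)
})

test_that("filter flags match the per-pair oracle on random pairs", {
  set.seed(31)
  n <- 400
  p <- data.table::data.table(
    read_id = sprintf("r%03d", seq_len(n)),
    chrom1 = "c", pos1 = sort(round(runif(n, 0, 1e6))), strand1 = sample(c("+", "-"), n, TRUE),
    chrom2 = sample(c("c", "d"), n, TRUE, prob = c(0.8, 0.2)),
    pos2 = round(runif(n, 0, 1e6)), strand2 = sample(c("+", "-"), n, TRUE),
    frag1 = sample(1:50, n, TRUE), frag2 = sample(1:50, n, TRUE),
    sitedist1 = round(runif(n, 0, 8e3)), sitedist2 = round(runif(n, 0, 8e3)))
  # canonical ordering before filtering
  swap <- p$chrom1 == p$chrom2 & p$pos1 > p$pos2
  tmp <- p$pos1[swap]; p$pos1[swap] <- p$pos2[swap]; p$pos2[swap] <- tmp
  tmp <- p$strand1[swap]; p$strand1[swap] <- p$strand2[swap]; p$strand2[swap] <- tmp
  pf <- filter_pairs(data.table::copy(p))
  for (i in seq_len(n)) {
    want <- oracle_filter_flags(p[i])
    expect_equal(pf$same_fragment[i], "same_fragment" %in% want)
    expect_equal(pf$far_from_site[i], "far_from_site" %in% want)
    expect_equal(pf$inward_short[i], "inward_short" %in% want)
    expect_equal(pf$outward_short[i], "outward_short" %in% want)
  }
})

test_that("deduplication matches definitions and the brute-force oracle", {
  base <- data.table::data.table(read_id = c("a", "b"),
    chrom1 = "c1", pos1 = c(100, 101), strand1 = "+",
    chrom2 = "c2", pos2 = c(200, 199), strand2 = "-")
  expect_equal(deduplicate(data.table::copy(base))$duplicate, c(FALSE, TRUE))

  b2 <- data.table::copy(base); b2$pos1 <- c(100, 103); b2$pos2 <- c(200, 200)
  expect_equal(deduplicate(b2)$duplicate, c(FALSE, FALSE))

  # k identical copies -> one retained
  k <- 5
  bk <- base[rep(1, k)]; bk$read_id <- letters[1:k]
  expect_equal(sum(deduplicate(bk)$duplicate), k - 1)

  # random clustered pairs vs O(n^2) oracle
  set.seed(7)
  n <- 300
  p <- data.table::data.table(read_id = as.character(seq_len(n)),
    chrom1 = "c1", pos1 = sample(1:150, n, TRUE), strand1 = sample(c("+", "-"), n, TRUE),
    chrom2 = "c1", pos2 = sample(1:150, n, TRUE), strand2 = sample(c("+", "-"), n, TRUE))
  expect_equal(deduplicate(data.table::copy(p))$duplicate, oracle_dedup(p))
})

test_that("dedup retained loci are stable under permutation of non-duplicates", {
  set.seed(8)
  n <- 60
  p <- data.table::data.table(read_id = as.character(seq_len(n)),
    chrom1 = "c1", pos1 = sample(seq(0, 6000, by = 10), n), strand1 = "+",
    chrom2 = "c1", pos2 = sample(seq(0, 6000, by = 10), n), strand2 = "+")
  # spacing 10 > 2 * tolerance: no duplicates at all, any order
  d1 <- deduplicate(data.table::copy(p))
  d2 <- deduplicate(p[sample.int(n)])
  expect_false(any(d1$duplicate) || any(d2$duplicate))
})

test_that("pair statistics respect first-trigger accounting", {
  p <- data.table::data.table(read_id = c("a", "b", "c"),
    chrom1 = "c1", pos1 = c(100, 200, 5e5), strand1 = c("+", "+", "+"),
    chrom2 = c("c1", "c1", "c2"), pos2 = c(5e3, 5e5, 100), strand2 = c("-", "+", "+"),
    frag1 = c(1, 2, 3), frag2 = c(1, 9, 20),
    sitedist1 = c(10, 6e3, 10), sitedist2 = c(10, 10, 10))
  p <- filter_pairs(p)
  p <- deduplicate(p)
  p <- apply_filter_precedence(p)
  # pair a is same_fragment AND inward_short: same_fragment wins
  expect_equal(p$filter, c("same_fragment", "far_from_site", "valid"))
  st <- pair_stats(p, n_low_mapq = 2L)
  expect_equal(st$total, 5L)
  expect_equal(st$valid +
    sum(unlist(st$filtered)) + st$low_mapq, st$total)
  expect_equal(st$cis, 0L)
  expect_equal(st$trans, 1L)
})

test_that("cis/trans ratios follow the possible-contact normalisation", {
  st <- list(cis = 80, trans = 20)
  b <- make_bins(c(c1 = 100e3, c2 = 100e3), 50e3)
  ct <- cis_trans_ratio(st, b)
  expect_equal(ct$raw, 4)
  # two chromosomes of 2 bins: intra 6, inter 4 -> f = 1.5
  expect_equal(ct$f, 1.5)
  expect_equal(cis_trans_ratio(list(cis = 6, trans = 4), b)$normalised, 1)
  expect_true(is.na(cis_trans_ratio(list(cis = 5, trans = 0), b)$raw))
})
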