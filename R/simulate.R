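#' Contact-map simulation specification
#'
#' The stated world for the simulator: a small two-chromosome genome at
#' 50 kb resolution with power-law distance decay, optional TAD blocks,
#' loop foci, compartment checkerboards and masked bins, sampled with
#' Poisson noise at a fixed sequencing depth. Same seed, same output.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp (default
#'   two 20 Mb chromosomes, 400 bins each at 50 kb).
#' @param resolution bin size in bp (default 50 kb).
#' @param alpha distance-decay exponent (default 1, the classic
#'   fractal-globule scaling).
#' @param depth total expected pair count (default 2e6).
#' @param tads data.frame `chrom`, `start`, `end`, `multiplier` or NULL.
#' @param loops data.frame `chrom`, `pos1`, `pos2`, `fold` or NULL.
#' @param compartments per-bin label vector ("A"/"B"/NA) or NULL; see
#'   [checkerboard_labels()].
#' @param comp_same,comp_cross compartment multipliers for same-/cross-label
#'   bin pairs (defaults 1.5 and 0.67).
#' @param trans_level inter-chromosomal weight relative to the cis decay
#'   unit (default 0.003, giving a realistic cis/trans balance at the
#'   default genome).
#' @param masked_fraction fraction of bins zeroed to emulate unmappable
#'   regions (default 0).
#' @param loop_sigma Gaussian loop-focus width in bins (default 1).
#' @param seed mandatory RNG seed.
#' @return list of class `map_spec`.
#' @export
map_spec <- function(chrom_lengths = c(chrA = 20e6, chrB = 20e6),
                     resolution = 50e3, alpha = 1, depth = 2e6,
                     tads = NULL, loops = NULL, compartments = NULL,
                     comp_same = 1.5, comp_cross = 0.67,
                     trans_level = 0.003, masked_fraction = 0,
                     loop_sigma = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(tads) && any(tads$multiplier <= 0)) stop("TAD multipliers must be > 0")
  if (!is.null(loops) && any(loops$fold <= 0)) stop("loop folds must be > 0")
  structure(list(chrom_lengths = chrom_lengths, resolution = resolution,
                 alpha = alpha, depth = depth, tads = tads, loops = loops,
                 compartments = compartments, comp_same = comp_same,
                 comp_cross = comp_cross, trans_level = trans_level,
                 masked_fraction = masked_fraction, loop_sigma = loop_sigma,
                 seed = as.integer(seed)),
            class = "map_spec")
}

#' Alternating A/B labels for a bin table
#'
#' @param bins `bin_table`.
#' @param block_bins compartment block size in bins (default 20, i.e. 1 Mb
#'   at 50 kb).
#' @return character vector of "A"/"B" per bin (alternating per
#'   chromosome).
#' @export
checkerboard_labels <- function(bins, block_bins = 20L) {
  cid <- same_chrom_bins(bins)
  lab <- character(nrow(bins))
  for (ch in unique(cid)) {
    sel <- which(cid == ch)
    lab[sel] <- c("A", "B")[(floor((seq_along(sel) - 1) / block_bins) %% 2) + 1]
  }
  lab
}

# expected-intensity weight matrix of a map spec (before depth scaling)
lambda_weights <- function(spec, bins) {
  N <- nrow(bins)
  cid <- same_chrom_bins(bins)
  w <- matrix(spec$trans_level, N, N)
  for (ch in unique(cid)) {
    sel <- which(cid == ch)
    n <- length(sel)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w[sel, sel] <- (d + 1)^(-spec$alpha)
  }
  if (!is.null(spec$tads)) {
    for (r in seq_len(nrow(spec$tads))) {
      sel <- which(bins$chrom == spec$tads$chrom[r] &
                   bins$start >= spec$tads$start[r] &
                   bins$end <= spec$tads$end[r])
      w[sel, sel] <- w[sel, sel] * spec$tads$multiplier[r]
    }
  }
  if (!is.null(spec$compartments)) {
    lab <- spec$compartments
    for (ch in unique(cid)) {
      sel <- which(cid == ch)
      l <- lab[sel]
      same <- outer(l, l, "==")
      def <- !outer(is.na(l), is.na(l), "|")
      f <- matrix(1, length(sel), length(sel))
      f[def & same] <- spec$comp_same
      f[def & !same] <- spec$comp_cross
      w[sel, sel] <- w[sel, sel] * f
    }
  }
  if (!is.null(spec$loops)) {
    for (r in seq_len(nrow(spec$loops))) {
      b1 <- locate_bins(bins, spec$loops$chrom[r], spec$loops$pos1[r])
      b2 <- locate_bins(bins, spec$loops$chrom[r], spec$loops$pos2[r])
      sel <- which(cid == cid[b1])
      i <- matrix(sel, length(sel), length(sel))
      j <- t(i)
      r2a <- (i - b1)^2 + (j - b2)^2
      r2b <- (i - b2)^2 + (j - b1)^2
      bump <- 1 + (spec$loops$fold[r] - 1) *
        (exp(-r2a / (2 * spec$loop_sigma^2)) + exp(-r2b / (2 * spec$loop_sigma^2)))
      w[sel, sel] <- w[sel, sel] * pmin(bump, spec$loops$fold[r])
    }
  }
  w
}

#' Simulate a raw contact map with planted ground truth
#'
#' Builds the expected intensity `lambda[i,j] = decay x TAD x compartment x
#' loop` scaled so the upper-triangle mass equals the target depth, then
#' draws independent Poisson counts per pixel. Masked bins are zeroed.
#'
#' @param spec a [map_spec()].
#' @return list: `matrix` (raw `contact_matrix`), `truth` (the spec plus
#'   planted bin-level records: TAD/loop bins, labels, masked bins).
#' @export
simulate_contact_map <- function(spec) {
  set.seed(spec$seed)
  bins <- make_bins(spec$chrom_lengths, spec$resolution)
  N <- nrow(bins)
  w <- lambda_weights(spec, bins)
  up <- upper.tri(w, diag = TRUE)
  lam <- w * spec$depth / sum(w[up])
  counts <- matrix(0, N, N)
  counts[up] <- stats::rpois(sum(up), lam[up])
  counts <- counts + t(counts)
  diag(counts) <- diag(counts) / 2
  masked <- integer(0)
  if (spec$masked_fraction > 0) {
    masked <- sort(sample.int(N, floor(spec$masked_fraction * N)))
    counts[masked, ] <- 0
    counts[, masked] <- 0
  }
  m <- contact_matrix(counts, bins, state = "raw")
  truth <- list(spec = spec, masked_bins = masked,
                tad_bins = if (!is.null(spec$tads))
                  lapply(seq_len(nrow(spec$tads)), function(r)
                    which(bins$chrom == spec$tads$chrom[r] &
                          bins$start >= spec$tads$start[r] &
                          bins$end <= spec$tads$end[r])) else list(),
                loop_bins = if (!is.null(spec$loops))
                  data.table::data.table(
                    bin1 = locate_bins(bins, spec$loops$chrom, spec$loops$pos1),
                    bin2 = locate_bins(bins, spec$loops$chrom, spec$loops$pos2))
                  else NULL,
                labels = spec$compartments)
  list(matrix = m, truth = truth)
}

#' Rearrangement specification
#'
#' @param chromA,chromB partner chromosomes.
#' @param bpA,bpB breakpoint positions in bp.
#' @param reciprocal both derivative chromosomes present (default TRUE);
#'   otherwise only the der(A) fusion quadrant receives signal.
#' @param intensity cis-decay scale of the fusion signal relative to the
#'   map's own decay (default 0.5: one rearranged allele of two).
#' @param lost intervals (data.frame `chrom`, `start`, `end`) whose
#'   rows/columns are halved, emulating one-allele loss between
#'   breakpoints; NULL for none.
#' @return list of class `rearrangement_spec`.
#' @export
rearrangement_spec <- function(chromA, chromB, bpA, bpB, reciprocal = TRUE,
                               intensity = 0.5, lost = NULL) {
  structure(list(chromA = chromA, chromB = chromB, bpA = bpA, bpB = bpB,
                 reciprocal = reciprocal, intensity = intensity, lost = lost),
            class = "rearrangement_spec")
}

#' Inject a translocation into a simulated raw map
#'
#' Adds cis-like decaying Poisson signal to the inter-chromosomal block of
#' the two partner chromosomes, anchored at the breakpoints. For a
#' reciprocal t(A;B) the der(A) quadrant (A upstream of the breakpoint
#' joined to B downstream) and the der(B) quadrant (A downstream joined to
#' B upstream) both receive signal; a one-sided fusion fills only der(A).
#' The decay amplitude is taken from the map's own per-distance mean raw
#' counts so the fusion looks like genuine cis contacts. Optional lost
#' segments have their rows/columns halved (binomial thinning).
#'
#' @param sim output of [simulate_contact_map()] (or a raw
#'   `contact_matrix`).
#' @param rspec a [rearrangement_spec()].
#' @param seed RNG seed for the added counts.
#' @return list: `matrix` (rearranged raw `contact_matrix`), `truth` with
#'   breakpoint bins.
#' @export
inject_translocation <- function(sim, rspec, seed = 1L) {
  m <- if (inherits(sim, "contact_matrix")) sim else sim$matrix
  bins <- m$bins
  cs <- attr(bins, "chroms")
  if (rspec$bpA < 0 || rspec$bpA > cs$lengths[match(rspec$chromA, cs$names)] ||
      rspec$bpB < 0 || rspec$bpB > cs$lengths[match(rspec$chromB, cs$names)])
    stop("breakpoint outside chromosome")
  set.seed(seed)
  counts <- m$mat
  selA <- which(bins$chrom == rspec$chromA)
  selB <- which(bins$chrom == rspec$chromB)
  bA <- locate_bins(bins, rspec$chromA, min(rspec$bpA, cs$lengths[match(rspec$chromA, cs$names)] - 1))
  bB <- locate_bins(bins, rspec$chromB, min(rspec$bpB, cs$lengths[match(rspec$chromB, cs$names)] - 1))
  # per-distance mean raw counts from the map's own cis signal
  dmax <- max(length(selA), length(selB))
  cd <- numeric(dmax)
  nd <- numeric(dmax)
  for (sel in list(selA, selB)) {
    sub <- counts[sel, sel]
    n <- length(sel)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      cd[d + 1] <- cd[d + 1] + sum(sub[cbind(i, i + d)])
      nd[d + 1] <- nd[d + 1] + length(i)
    }
  }
  cd <- ifelse(nd > 0, cd / nd, 0)
  decay_at <- function(d) cd[pmin(d, dmax - 1L) + 1L]
  posA <- seq_along(selA); posB <- seq_along(selB)
  dA <- matrix(posA - (bA - min(selA) + 1L), length(selA), length(selB))
  dB <- t(matrix(posB - (bB - min(selB) + 1L), length(selB), length(selA)))
  lamT <- matrix(0, length(selA), length(selB))
  # der(A): A-side upstream of bpA fused to B-side downstream of bpB;
  # derivative distance = |distance to bpA| + |distance to bpB|
  q1 <- dA <= 0 & dB >= 0
  lamT[q1] <- rspec$intensity * decay_at(abs(dA[q1]) + abs(dB[q1]))
  if (rspec$reciprocal) {
    q2 <- dA >= 0 & dB <= 0
    lamT[q2] <- pmax(lamT[q2], rspec$intensity * decay_at(abs(dA[q2]) + abs(dB[q2])))
  }
  add <- matrix(stats::rpois(length(lamT), lamT), nrow(lamT), ncol(lamT))
  counts[selA, selB] <- counts[selA, selB] + add
  counts[selB, selA] <- t(counts[selA, selB])
  if (!is.null(rspec$lost)) {
    for (r in seq_len(nrow(rspec$lost))) {
      sel <- which(bins$chrom == rspec$lost$chrom[r] &
                   bins$start >= rspec$lost$start[r] &
                   bins$end <= rspec$lost$end[r])
      # binomial thinning of the upper triangle touching `sel`, mirrored to
      # keep the matrix symmetric
      touch <- which(upper.tri(counts, diag = TRUE) &
                     (row(counts) %in% sel | col(counts) %in% sel))
      counts[touch] <- stats::rbinom(length(touch), as.integer(counts[touch]), 0.5)
      lower <- lower.tri(counts)
      counts[lower] <- t(counts)[lower]
    }
  }
  out <- contact_matrix(counts, bins, state = "raw")
  list(matrix = out,
       truth = list(rspec = rspec, bpA_bin = bA, bpB_bin = bB))
}

#' Read-pair simulation specification
#'
#' @param fragments `fragment_map` of the synthetic genome.
#' @param n total pair count.
#' @param frac_duplicate,frac_self_ligation,frac_unligated,frac_same_fragment,frac_trans
#'   planted artefact fractions (of `n`); must sum to <= 1 (remainder:
#'   valid cis pairs).
#' @param seed RNG seed.
#' @return list of class `pair_sim_spec`.
#' @export
pair_sim_spec <- function(fragments, n, frac_duplicate = 0,
                          frac_self_ligation = 0, frac_unligated = 0,
                          frac_same_fragment = 0, frac_trans = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(frac_duplicate, frac_self_ligation, frac_unligated, frac_same_fragment)
  if (any(fr < 0) || sum(fr) > 1) stop("artefact fractions must be >= 0 and sum <= 1")
  structure(list(fragments = fragments, n = as.integer(n),
                 frac_duplicate = frac_duplicate,
                 frac_self_ligation = frac_self_ligation,
                 frac_unligated = frac_unligated,
                 frac_same_fragment = frac_same_fragment,
                 frac_trans = frac_trans, seed = as.integer(seed)),
            class = "pair_sim_spec")
}

#' Simulate aligned read pairs with planted artefacts
#'
#' Valid pairs are drawn between random loci with a heavy-tailed
#' distance-decaying separation (at least the 10 kb orientation cutoff, so
#' orientation flags only fire on planted artefacts); artefact classes are
#' generated to their definitions: duplicates are jittered copies
#' (<= 2 bp) of already-drawn pairs, self-ligations are outward-facing
#' pairs under 10 kb, unligated fragments inward-facing under 10 kb, and
#' same-fragment pairs have both loci on one restriction fragment.
#'
#' @param spec a [pair_sim_spec()].
#' @return list: `reads` (aligned-read table, two records per pair),
#'   `truth` (data.table `read_id`, `label`).
#' @export
simulate_read_pairs <- function(spec) {
  set.seed(spec$seed)
  frg <- spec$fragments
  cs <- attr(frg, "chroms")
  n <- spec$n
  n_dup <- round(spec$frac_duplicate * n)
  n_self <- round(spec$frac_self_ligation * n)
  n_unlig <- round(spec$frac_unligated * n)
  n_same <- round(spec$frac_same_fragment * n)
  n_valid <- n - n_dup - n_self - n_unlig - n_same
  stopifnot(n_valid >= 0)

  rand_chrom <- function(k) sample(cs$names, k, replace = TRUE,
                                   prob = cs$lengths / sum(cs$lengths))
  rand_strand <- function(k) sample(c("+", "-"), k, replace = TRUE)
  clen <- function(chr) cs$lengths[match(chr, cs$names)]

  # valid pairs: cis with pareto-like separation >= 10 kb, or trans
  trans <- stats::runif(n_valid) < spec$frac_trans
  c1 <- rand_chrom(n_valid)
  c2 <- ifelse(trans, rand_chrom(n_valid), c1)
  sep <- pmin(10e3 * stats::runif(n_valid)^(-0.8), clen(c1) * 0.8)
  p1 <- floor(stats::runif(n_valid) * pmax(clen(c1) - sep - 1, 1))
  p2 <- ifelse(trans, floor(stats::runif(n_valid) * (clen(c2) - 1)),
               p1 + floor(sep))
  valid <- data.table::data.table(chrom1 = c1, pos1 = p1, strand1 = rand_strand(n_valid),
                                  chrom2 = c2, pos2 = p2, strand2 = rand_strand(n_valid),
                                  label = "valid")

  artefact <- function(k, sep_max, s1, s2, label) {
    if (k == 0L) return(NULL)
    ch <- rand_chrom(k)
    sep <- floor(stats::runif(k, 200, sep_max))
    p1 <- floor(stats::runif(k) * (clen(ch) - sep - 1))
    data.table::data.table(chrom1 = ch, pos1 = p1, strand1 = s1,
                           chrom2 = ch, pos2 = p1 + sep, strand2 = s2,
                           label = label)
  }
  selflig <- artefact(n_self, 9.5e3, "-", "+", "self_ligation")
  unlig <- artefact(n_unlig, 9.5e3, "+", "-", "unligated")

  samefrag <- NULL
  if (n_same > 0L) {
    fi <- sample.int(nrow(frg), n_same, replace = TRUE, prob = frg$end - frg$start)
    fl <- frg$end[fi] - frg$start[fi]
    o1 <- floor(stats::runif(n_same) * fl)
    o2 <- floor(stats::runif(n_same) * fl)
    samefrag <- data.table::data.table(
      chrom1 = frg$chrom[fi], pos1 = frg$start[fi] + pmin(o1, o2),
      strand1 = rand_strand(n_same),
      chrom2 = frg$chrom[fi], pos2 = frg$start[fi] + pmax(o1, o2),
      strand2 = rand_strand(n_same), label = "same_fragment")
  }

  base <- data.table::rbindlist(list(valid, selflig, unlig, samefrag))
  dups <- NULL
  if (n_dup > 0L) {
    src <- base[sample.int(nrow(base), n_dup, replace = TRUE)]
    jitter <- function(k) sample(-2:2, k, replace = TRUE)
    dups <- data.table::copy(src)
    dups[, `:=`(pos1 = pmax(0, pos1 + jitter(.N)),
                pos2 = pmax(0, pos2 + jitter(.N)), label = "duplicate")]
  }
  all_pairs <- data.table::rbindlist(list(base, dups))
  # duplicates must come after their source (greedy first-seen dedup);
  # shuffle originals and append duplicates in shuffled order
  ord <- c(sample.int(nrow(base)), nrow(base) + sample.int(max(n_dup, 0L)))
  all_pairs <- all_pairs[ord]
  all_pairs[, read_id := sprintf("sim%07d", .I)]
  reads <- data.table::rbindlist(list(
    all_pairs[, .(read_id, chrom = chrom1, pos = pos1, strand = strand1)],
    all_pairs[, .(read_id, chrom = chrom2, pos = pos2, strand = strand2)]))
  reads[, mapq := 60L]
  data.table::setorderv(reads, "read_id")
  list(reads = reads[], truth = all_pairs[, .(read_id, label)])
}

#' Fit the distance-decay exponent of an expected profile
#'
#' Least-squares slope of `log(expected)` against `log(d + 1)` over the
#' given bin-distance range, pooled across chromosomes.
#'
#' @param profile an [expected_by_distance()] table.
#' @param dmin,dmax bin-distance range (defaults 1 and 100).
#' @return the fitted slope (the decay exponent is its negation).
#' @export
fit_decay_exponent <- function(profile, dmin = 1L, dmax = 100L) {
  sub <- profile[profile$d >= dmin & profile$d <= dmax &
                 is.finite(profile$expected) & profile$expected > 0 &
                 profile$n_possible > 0]
  stats::coef(stats::lm(log(sub$expected) ~ log(sub$d + 1)))[[2]]
}

#' Synthetic random genome sequences
#'
#' Uniform-random A/C/G/T sequences for the given chromosome lengths;
#' convenience input for [digest_genome()] in tests and simulations.
#'
#' @param chrom_lengths named vector of lengths in bp.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
random_genome <- function(chrom_lengths, seed) {
  set.seed(seed)
  vapply(chrom_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
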