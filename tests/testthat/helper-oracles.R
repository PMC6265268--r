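# Independent oracles used across the suite. These deliberately share no
# code with the package: naive loops and direct definitions only.

# all 0-based cut positions of `site` in `seq` by scanning every position
oracle_cut_positions <- function(seq, site, cut_offset) {
  seq <- toupper(seq); site <- toupper(site)
  L <- nchar(seq); k <- nchar(site)
  cuts <- numeric(0)
  for (p in seq_len(L - k + 1)) {
    if (substr(seq, p, p + k - 1) == site) cuts <- c(cuts, p - 1 + cut_offset)
  }
  cuts
}

# per-pair re-evaluation of the bias filters, straight from the definitions
oracle_filter_flags <- function(p, site_cut = 5000, orient_cut = 10000) {
  flags <- character(0)
  if (p$frag1 == p$frag2) flags <- c(flags, "same_fragment")
  if (p$sitedist1 > site_cut || p$sitedist2 > site_cut)
    flags <- c(flags, "far_from_site")
  if (p$chrom1 == p$chrom2 && p$strand1 != p$strand2 &&
      abs(p$pos2 - p$pos1) < orient_cut) {
    up <- if (p$pos1 <= p$pos2) p$strand1 else p$strand2
    if (up == "+") flags <- c(flags, "inward_short")
    else flags <- c(flags, "outward_short")
  }
  flags
}

# O(n^2) greedy duplicate clustering in input order
oracle_dedup <- function(pairs, tol = 2) {
  n <- nrow(pairs)
  dup <- logical(n)
  kept <- integer(0)
  for (i in seq_len(n)) {
    isdup <- FALSE
    for (k in kept) {
      if (pairs$chrom1[i] == pairs$chrom1[k] &&
          pairs$chrom2[i] == pairs$chrom2[k] &&
          pairs$strand1[i] == pairs$strand1[k] &&
          pairs$strand2[i] == pairs$strand2[k] &&
          abs(pairs$pos1[i] - pairs$pos1[k]) <= tol &&
          abs(pairs$pos2[i] - pairs$pos2[k]) <= tol) { isdup <- TRUE; break }
    }
    if (isdup) dup[i] <- TRUE else kept <- c(kept, i)
  }
  dup
}

# symmetric Sinkhorn iteration toward unit row sums (independent of the
# package's internal fallback)
oracle_sinkhorn <- function(A, iters = 20000, tol = 1e-12) {
  x <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    r <- as.vector(A %*% x) * x
    x <- x / sqrt(r)
    if (max(abs(as.vector(A %*% x) * x - 1)) < tol) break
  }
  x
}

# brute-force HICCUPS neighbourhood membership by explicit conditions
oracle_masks <- function(p, w) {
  donut <- ll <- horiz <- vert <- NULL
  for (a in -w:w) for (b in -w:w) {
    in_outer <- max(abs(a), abs(b)) <= w
    in_inner <- max(abs(a), abs(b)) <= p
    if (in_outer && !in_inner && a != 0 && b != 0)
      donut <- rbind(donut, c(a, b))
    if (a >= 1 && a <= w && b <= -1 && b >= -w && !(a <= p && b >= -p))
      ll <- rbind(ll, c(a, b))
    if (abs(a) <= 1 && abs(b) > p && abs(b) <= w)
      horiz <- rbind(horiz, c(a, b))
    if (abs(b) <= 1 && abs(a) > p && abs(a) <= w)
      vert <- rbind(vert, c(a, b))
  }
  list(donut = donut, lower_left = ll, horizontal = horiz, vertical = vert)
}

# naive insulation: mean over the k x k square left x right of each bin
oracle_insulation_raw <- function(mat, k) {
  n <- nrow(mat)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - k < 1 || i + k > n) next
    vals <- c()
    for (r in (i - k):(i - 1)) for (cc in (i + 1):(i + k))
      vals <- c(vals, mat[r, cc])
    out[i] <- mean(vals)
  }
  out
}

sort_mask <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]

# tiny standard fixtures ----------------------------------------------------

toy_bins <- function(lengths = c(chrA = 500e3), bin = 50e3)
  make_bins(lengths, bin)

# exact distance-decay "balanced" matrix (no noise): M[i,j] = f(|i-j|)
decay_matrix <- function(n, f = function(d) 1 / (d + 1),
                         lengths = NULL, bin = 50e3, state = "balanced") {
  if (is.null(lengths)) lengths <- c(chrA = n * bin)
  bins <- make_bins(lengths, bin)
  stopifnot(nrow(bins) == n)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mat <- matrix(vapply(as.vector(d), f, numeric(1)), n, n)
  m <- contact_matrix(mat, bins, state = "raw")
  m$state <- state
  m$bias <- rep(1, n)
  m
}
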