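#' Library complexity curve
#'
#' Unique fragment-pair counts at down-sampled depths: for each depth,
#' draws that many pairs without replacement (seeded) and counts pairs that
#' are not duplicates of an earlier drawn pair (2 bp tolerance, the same
#' rule as [deduplicate()]). Library diversity is primarily a function of
#' depth, so the curve diagnoses PCR duplication independent of input
#' amount.
#'
#' @param pairs full pair table including duplicates.
#' @param depths vector of depths (each <= number of pairs).
#' @param seed sampling seed.
#' @param tolerance duplicate-matching tolerance in bp (default 2).
#' @return data.table with `depth`, `unique_pairs`, `seed`.
#' @export
complexity_curve <- function(pairs, depths, seed, tolerance = 2) {
  n <- nrow(pairs)
  if (any(depths > n)) stop("depth exceeds the number of pairs")
  set.seed(seed)
  perm <- sample.int(n)
  out <- lapply(sort(depths), function(d) {
    if (d == 0L) return(data.table::data.table(depth = 0L, unique_pairs = 0L))
    sub <- data.table::copy(pairs[perm[seq_len(d)]])
    sub <- deduplicate(sub, tolerance)
    data.table::data.table(depth = d, unique_pairs = sum(!sub$duplicate))
  })
  res <- data.table::rbindlist(out)
  res[, seed := seed]
  res[]
}

#' Match two libraries to the same valid-pair depth
#'
#' Down-samples the larger of two valid-pair sets (without replacement,
#' seeded) so both have the same count, the standard preparation before
#' comparing matrices of unequally deep libraries.
#'
#' @param a,b valid-pair tables.
#' @param seed sampling seed.
#' @return list of two tables of equal row count.
#' @export
match_depth <- function(a, b, seed) {
  set.seed(seed)
  n <- min(nrow(a), nrow(b))
  list(a = a[sample.int(nrow(a), n)], b = b[sample.int(nrow(b), n)])
}

#' Full library QC report
#'
#' @param pairs flagged pair table (after [process_pairs()]).
#' @param stats `pair_stats`.
#' @param bins `bin_table` for the cis/trans normalisation.
#' @param depths optional depths for the complexity curve.
#' @param seed seed for down-sampling.
#' @return list of class `qc_report`: `stats`, `cis_trans`,
#'   `complexity` (or NULL).
#' @export
qc_report <- function(pairs, stats, bins, depths = NULL, seed = 1L) {
  ct <- cis_trans_ratio(stats, bins)
  cc <- if (!is.null(depths)) complexity_curve(pairs, depths, seed) else NULL
  structure(list(stats = stats, cis_trans = ct, complexity = cc),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  print(x$stats)
  cat(sprintf("  cis/trans: raw %.3f, species-normalised %.3f (f=%.3f)\n",
              x$cis_trans$raw, x$cis_trans$normalised, x$cis_trans$f))
  if (!is.null(x$complexity))
    cat(sprintf("  complexity: %d depths up to %d\n",
                nrow(x$complexity), max(x$complexity$depth)))
  invisible(x)
}
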