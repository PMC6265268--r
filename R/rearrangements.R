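#' Virtual 4C profile of one viewpoint bin
#'
#' Row `i` of the genome-wide balanced matrix: the viewpoint's interaction
#' signal across every bin of every chromosome. Masked bins are `NA`.
#'
#' @param m genome-wide balanced `contact_matrix`.
#' @param i viewpoint bin (global index).
#' @return numeric vector of length `nbins`.
#' @export
v4c_profile <- function(m, i) {
  if (!m$bins$mappable[i]) stop("viewpoint bin ", i, " is masked")
  v <- m$mat[i, ]
  v[!m$bins$mappable] <- NA_real_
  v
}

#' Whole-genome virtual-4C peak scan
#'
#' Every mappable bin is used as a viewpoint in turn. A viewpoint is
#' skipped when any bin within `mappability_halfwidth` bins of it is
#' unmappable (mappability gaps produce false rearrangement signals). In a
#' viewpoint's profile `v`, bin `j` is a peak when `v_j` exceeds
#' `height_fraction * v_i` (the viewpoint height), strictly exceeds the
#' `percentile` quantile of all other defined entries of `v`, and is at
#' least `exclusion` bins away from `i` when intra-chromosomal (local
#' contact enrichment is never a rearrangement signal; inter-chromosomal
#' peaks are always far).
#'
#' @param m genome-wide balanced `contact_matrix` (50 kb scan resolution in
#'   the reference workflow).
#' @param height_fraction default 0.15.
#' @param percentile default 99.5 (percent).
#' @param exclusion intra-chromosomal exclusion radius in bins (default 50).
#' @param mappability_halfwidth default 7 bins.
#' @return data.table of peaks: `viewpoint`, `target` (global bins),
#'   `v_i`, `v_j`, `quantile_cut`.
#' @export
v4c_peak_scan <- function(m, height_fraction = 0.15, percentile = 99.5,
                          exclusion = 50L, mappability_halfwidth = 7L) {
  stopifnot(m$state %in% c("balanced", "raw"))
  N <- nrow(m$bins)
  cid <- same_chrom_bins(m$bins)
  map <- m$bins$mappable
  # viewpoint eligibility: the +/- halfwidth window, clipped at genome/
  # chromosome ends, must be fully mappable
  ok_vp <- vapply(seq_len(N), function(i) {
    win <- max(1L, i - mappability_halfwidth):min(N, i + mappability_halfwidth)
    win <- win[cid[win] == cid[i]]
    all(map[win])
  }, logical(1)) & map
  out <- list()
  for (i in which(ok_vp)) {
    v <- m$mat[i, ]
    v[!map] <- NA_real_
    vi <- v[i]
    if (!is.finite(vi) || vi <= 0) next
    others <- v[-i]
    qcut <- stats::quantile(others, percentile / 100, na.rm = TRUE, names = FALSE)
    far <- cid != cid[i] | abs(seq_len(N) - i) >= exclusion
    hit <- which(is.finite(v) & far & seq_len(N) != i &
                 v > height_fraction * vi & v > qcut)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        viewpoint = i, target = hit, v_i = vi, v_j = v[hit], quantile_cut = qcut)
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(viewpoint = integer(), target = integer(),
                           v_i = numeric(), v_j = numeric(),
                           quantile_cut = numeric())
  data.table::setattr(res, "class", c("v4c_peaks", class(res)))
  res[]
}

#' Case-vs-control comparison of V4C scans
#'
#' Keeps case peaks with no control peak whose viewpoint and target both
#' lie within `tolerance` bins, then merges retained peaks into calls:
#' connected runs where both viewpoint and target bins are within
#' `merge_gap` bins of another member. Each call reports its viewpoint and
#' target block, the supporting peak count, and a refined breakpoint —
#' the member pixel with the strongest target signal, where a
#' translocation's cis-like decay is anchored.
#'
#' @param case_peaks,control_peaks outputs of [v4c_peak_scan()] on
#'   identically binned matrices.
#' @param tolerance control-matching tolerance in bins (default 2).
#' @param merge_gap adjacency gap for merging case peaks (default 1 bin).
#' @return data.table `rearrangement_calls`: viewpoint/target block bounds
#'   (global bins), `n_peaks`, `bp_viewpoint`, `bp_target`, `max_vj`.
#' @export
compare_scans <- function(case_peaks, control_peaks, tolerance = 2L,
                          merge_gap = 1L) {
  cp <- data.table::as.data.table(case_peaks)
  if (nrow(cp) == 0L) return(empty_calls())
  if (nrow(control_peaks) > 0L) {
    keep <- vapply(seq_len(nrow(cp)), function(r) {
      !any(abs(control_peaks$viewpoint - cp$viewpoint[r]) <= tolerance &
           abs(control_peaks$target - cp$target[r]) <= tolerance)
    }, logical(1))
    cp <- cp[keep]
  }
  if (nrow(cp) == 0L) return(empty_calls())
  # single-linkage clustering in (viewpoint, target) space
  n <- nrow(cp)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (a in seq_len(max(n - 1L, 0L))) {
    for (b in (a + 1L):n) {
      if (abs(cp$viewpoint[a] - cp$viewpoint[b]) <= merge_gap &&
          abs(cp$target[a] - cp$target[b]) <= merge_gap) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) comp[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  calls <- data.table::rbindlist(lapply(split(seq_len(n), root), function(rows) {
    sub <- cp[rows]
    best <- which.max(sub$v_j)
    data.table::data.table(
      viewpoint_from = min(sub$viewpoint), viewpoint_to = max(sub$viewpoint),
      target_from = min(sub$target), target_to = max(sub$target),
      n_peaks = nrow(sub),
      bp_viewpoint = sub$viewpoint[best], bp_target = sub$target[best],
      max_vj = sub$v_j[best])
  }))
  data.table::setorderv(calls, c("viewpoint_from", "target_from"))
  data.table::setattr(calls, "class", c("rearrangement_calls", class(calls)))
  calls[]
}

empty_calls <- function() {
  res <- data.table::data.table(
    viewpoint_from = integer(), viewpoint_to = integer(),
    target_from = integer(), target_to = integer(), n_peaks = integer(),
    bp_viewpoint = integer(), bp_target = integer(), max_vj = numeric())
  data.table::setattr(res, "class", c("rearrangement_calls", class(res)))
  res[]
}

#' Merge two boundary sets
#'
#' Sorted union of boundary bins from two samples; boundaries within
#' `collapse` bins of each other are collapsed to one (the smaller bin).
#'
#' @param a,b `boundary_set` tables (or vectors of bins).
#' @param collapse collapse distance in bins (default 1).
#' @return integer vector of merged boundary bins.
#' @export
merge_boundaries <- function(a, b, collapse = 1L) {
  bins <- sort(unique(c(if (is.data.frame(a)) a$bin else a,
                        if (is.data.frame(b)) b$bin else b)))
  if (length(bins) <= 1L) return(bins)
  keep <- c(TRUE, diff(bins) > collapse)
  bins[keep]
}

#' TAD intensity difference between case and control
#'
#' Boundaries from both samples are merged (union, collapsing boundaries
#' within 1 bin), and for every region between two consecutive merged
#' boundaries the mean signal over all pixel pairs inside the region's
#' square sub-matrix is computed per sample; the difference is
#' case minus control.
#'
#' @param case,control `contact_matrix` objects on identical bins
#'   (balanced).
#' @param case_boundaries,control_boundaries `boundary_set` tables from
#'   [call_boundaries()].
#' @param collapse boundary collapse distance in bins (default 1).
#' @return data.table: `chrom`, `from_bin`, `to_bin`, `mean_case`,
#'   `mean_control`, `difference`.
#' @export
tad_intensity_difference <- function(case, control, case_boundaries,
                                     control_boundaries, collapse = 1L) {
  check_same_bins(case, control)
  cid <- same_chrom_bins(case$bins)
  out <- list()
  for (ch in unique(cid)) {
    sel <- which(cid == ch)
    onchr <- function(bs) bs[bs$bin %in% sel]
    merged <- merge_boundaries(onchr(case_boundaries), onchr(control_boundaries),
                               collapse)
    if (length(merged) < 2L) next
    for (k in seq_len(length(merged) - 1L)) {
      rng <- merged[k]:merged[k + 1L]
      mc <- mean(case$mat[rng, rng], na.rm = TRUE)
      mk <- mean(control$mat[rng, rng], na.rm = TRUE)
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = case$bins$chrom[merged[k]],
        from_bin = merged[k], to_bin = merged[k + 1L],
        mean_case = mc, mean_control = mk, difference = mc - mk)
    }
  }
  if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), from_bin = integer(),
                           to_bin = integer(), mean_case = numeric(),
                           mean_control = numeric(), difference = numeric())
}
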