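#' Nearest-neighbour resampling of a matrix to a fixed grid
#'
#' Maps each output pixel to the nearest input pixel (by fractional index),
#' the same scheme as image-resize with a "nearest" kernel. Used to bring
#' differently sized sub-matrices onto one averaging grid.
#'
#' @param mat numeric matrix.
#' @param grid output side length in pixels.
#' @return `grid x grid` numeric matrix.
#' @export
resample_nearest <- function(mat, grid) {
  n <- nrow(mat); m <- ncol(mat)
  ri <- pmin(n, pmax(1L, floor((seq_len(grid) - 0.5) * n / grid) + 1L))
  ci <- pmin(m, pmax(1L, floor((seq_len(grid) - 0.5) * m / grid) + 1L))
  mat[ri, ci, drop = FALSE]
}

#' Aggregate TAD pileup
#'
#' For each region, extracts the square O/E sub-matrix covering the region
#' expanded to `expand` times its size (centred), resamples it to a fixed
#' `grid x grid` and averages elementwise over regions. Instances with more
#' than half their pixels undefined, or whose expanded window exits the
#' chromosome, are skipped and counted.
#'
#' @param oe `contact_matrix` in `"oe"` state.
#' @param regions data.frame with `chrom`, `start`, `end` (bp,
#'   0-based half-open), intra-chromosomal.
#' @param expand window size as a multiple of region size (default 3).
#' @param grid output grid side (default 90).
#' @return list (`aggregate_result`): `matrix` (grid x grid mean),
#'   `n_used`, `n_skipped`.
#' @export
aggregate_tads <- function(oe, regions, expand = 3, grid = 90L) {
  stopifnot(oe$state == "oe")
  if (nrow(regions) == 0L) stop("empty region list")
  acc <- matrix(0, grid, grid); cnt <- matrix(0, grid, grid)
  used <- 0L; skipped <- 0L
  res <- oe$resolution
  for (r in seq_len(nrow(regions))) {
    centre <- (regions$start[r] + regions$end[r]) / 2
    half <- (regions$end[r] - regions$start[r]) * expand / 2
    sub <- extract_square(oe, regions$chrom[r], centre - half, centre + half)
    if (is.null(sub) || mean(!is.finite(sub)) > 0.5) { skipped <- skipped + 1L; next }
    rs <- resample_nearest(sub, grid)
    ok <- is.finite(rs)
    acc[ok] <- acc[ok] + rs[ok]; cnt[ok] <- cnt[ok] + 1
    used <- used + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  structure(list(matrix = out, n_used = used, n_skipped = skipped),
            class = "aggregate_result")
}

# square sub-matrix [start, end) x [start, end) on one chromosome;
# NULL when the window exits the chromosome
extract_square <- function(m, chrom, start, end) {
  cs <- attr(m$bins, "chroms")
  k <- match(chrom, cs$names)
  if (is.na(k)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > cs$lengths[k]) return(NULL)
  sel <- which(m$bins$chrom == chrom &
               m$bins$start < end & m$bins$end > start)
  if (length(sel) == 0L) return(NULL)
  m$mat[sel, sel, drop = FALSE]
}

#' TAD strength
#'
#' Ratio of the summed O/E signal inside the TAD square to the average of
#' the two neighbouring squares of the same size — the classic
#' single-region domain-strength statistic. Scale-invariant by
#' construction.
#'
#' @param oe `contact_matrix` in `"oe"` state.
#' @param chrom,start,end TAD interval (bp, 0-based half-open).
#' @return scalar strength, or `NA` with a warning when a neighbour square
#'   exits the chromosome.
#' @export
tad_strength <- function(oe, chrom, start, end) {
  stopifnot(oe$state == "oe")
  w <- end - start
  left <- extract_square(oe, chrom, start - w, start)
  mid <- extract_square(oe, chrom, start, end)
  right <- extract_square(oe, chrom, end, end + w)
  if (is.null(left) || is.null(right) || is.null(mid)) {
    warning("neighbour region exits chromosome; TAD strength undefined")
    return(NA_real_)
  }
  s <- sum(mid, na.rm = TRUE)
  flank <- 0.5 * (sum(left, na.rm = TRUE) + sum(right, na.rm = TRUE))
  if (flank <= 0) return(NA_real_)
  s / flank
}

#' Aggregate loop pileup
#'
#' For each anchor pair, extracts the O/E window of `window` bp centred on
#' the (anchor1, anchor2) pixel and averages over pairs. Windows that exit
#' the matrix are skipped and counted.
#'
#' @param oe `contact_matrix` in `"oe"` state.
#' @param anchors data.frame with `chrom`, `pos1`, `pos2` (bp anchor
#'   midpoints, intra-chromosomal, pos1 < pos2).
#' @param window window size in bp (default 400 kb, i.e. centre +/- 8 bins
#'   at 25 kb).
#' @return `aggregate_result` list.
#' @export
aggregate_loops <- function(oe, anchors, window = 400e3) {
  stopifnot(oe$state == "oe")
  res <- oe$resolution
  hw <- floor(window / res / 2)
  side <- 2L * hw + 1L
  acc <- matrix(0, side, side); cnt <- matrix(0, side, side)
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(anchors))) {
    b1 <- locate_bins(oe$bins, anchors$chrom[r], anchors$pos1[r])
    b2 <- locate_bins(oe$bins, anchors$chrom[r], anchors$pos2[r])
    cid <- same_chrom_bins(oe$bins)
    sel <- which(cid == cid[b1])
    i <- b1 - min(sel) + 1L; j <- b2 - min(sel) + 1L
    n <- length(sel)
    if (i - hw < 1L || i + hw > n || j - hw < 1L || j + hw > n) {
      skipped <- skipped + 1L; next
    }
    sub <- oe$mat[sel[(i - hw):(i + hw)], sel[(j - hw):(j + hw)], drop = FALSE]
    if (mean(!is.finite(sub)) > 0.5) { skipped <- skipped + 1L; next }
    ok <- is.finite(sub)
    acc[ok] <- acc[ok] + sub[ok]; cnt[ok] <- cnt[ok] + 1
    used <- used + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  structure(list(matrix = out, n_used = used, n_skipped = skipped),
            class = "aggregate_result")
}

#' Loop strength
#'
#' Summed signal in the `window` bp square centred on the loop pixel
#' (anchor1, anchor2), divided by the average of two control squares at the
#' same diagonal distance: control 1 replaces anchor1 with the locus at
#' distance `d` on the far side of anchor2, control 2 replaces anchor2 with
#' the locus at distance `d` on the far side of anchor1 (`d` = anchor
#' separation). Computed on O/E by default (pass a balanced matrix to use
#' balanced signal); scale-invariant.
#'
#' @param m `contact_matrix` (O/E or balanced).
#' @param chrom,pos1,pos2 anchor midpoints in bp, pos1 < pos2.
#' @param window square size in bp (default 300 kb).
#' @return scalar strength, or `NA` with a warning when a control square
#'   exits the chromosome.
#' @export
loop_strength <- function(m, chrom, pos1, pos2, window = 300e3) {
  d <- pos2 - pos1
  stopifnot(d > 0)
  hw <- window / 2
  sq <- function(cx, cy) {
    a <- extract_rect(m, chrom, cx - hw, cx + hw, cy - hw, cy + hw)
    if (is.null(a)) NA_real_ else sum(a, na.rm = TRUE)
  }
  s <- sq(pos1, pos2)
  c1 <- sq(pos2, pos2 + d)   # anchor1 reflected past anchor2
  c2 <- sq(pos1 - d, pos1)   # anchor2 reflected before anchor1
  if (is.na(s) || is.na(c1) || is.na(c2)) {
    warning("control region exits chromosome; loop strength undefined")
    return(NA_real_)
  }
  flank <- 0.5 * (c1 + c2)
  if (flank <= 0) return(NA_real_)
  s / flank
}

extract_rect <- function(m, chrom, x0, x1, y0, y1) {
  cs <- attr(m$bins, "chroms")
  k <- match(chrom, cs$names)
  if (is.na(k)) stop("unknown chromosome: ", chrom)
  if (min(x0, y0) < 0 || max(x1, y1) > cs$lengths[k]) return(NULL)
  rows <- which(m$bins$chrom == chrom & m$bins$start < x1 & m$bins$end > x0)
  cols <- which(m$bins$chrom == chrom & m$bins$start < y1 & m$bins$end > y0)
  if (!length(rows) || !length(cols)) return(NULL)
  m$mat[rows, cols, drop = FALSE]
}
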