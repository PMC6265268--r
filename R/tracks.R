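#' Insulation score track
#'
#' Slides a square window of `window` bp along the matrix diagonal: the raw
#' score at bin `i` is the mean balanced signal over the square spanning the
#' `k` bins upstream versus the `k` bins downstream of `i` (the bin itself
#' excluded). Scores are undefined where the square exits the chromosome or
#' covers more than 50% masked pixels. The final track is
#' `log2(raw / chromosomal mean raw)`, so insulating bins (TAD boundaries)
#' show as minima and, per chromosome, the mean of `2^score` over defined
#' bins is 1.
#'
#' @param m balanced `contact_matrix`.
#' @param window window size in bp; must be a positive multiple of the
#'   resolution.
#' @return data.table `insulation_track` with columns `chrom`, `start`,
#'   `end`, `bin`, `score` (NA where undefined); attribute `window`.
#' @export
insulation_score <- function(m, window = 250e3) {
  k <- window / m$resolution
  if (k < 1 || k != round(k)) stop("window must be a positive multiple of the resolution")
  k <- as.integer(k)
  cid <- same_chrom_bins(m$bins)
  raw <- rep(NA_real_, nrow(m$bins))
  for (ch in unique(cid)) {
    sel <- which(cid == ch)
    n <- length(sel)
    sub <- m$mat[sel, sel, drop = FALSE]
    map <- m$bins$mappable[sel]
    for (i in seq_len(n)) {
      if (i - k < 1L || i + k > n) next
      rows <- (i - k):(i - 1L); cols <- (i + 1L):(i + k)
      ok <- outer(map[rows], map[cols], "&")
      if (sum(ok) < 0.5 * k * k) next
      raw[sel[i]] <- mean(sub[rows, cols][ok])
    }
    ri <- raw[sel]
    mu <- mean(ri, na.rm = TRUE)
    raw[sel] <- if (is.finite(mu) && mu > 0) log2(ri / mu) else NA_real_
  }
  out <- data.table::data.table(chrom = m$bins$chrom, start = m$bins$start,
                                end = m$bins$end, bin = m$bins$bin, score = raw)
  data.table::setattr(out, "window", window)
  data.table::setattr(out, "chroms", attr(m$bins, "chroms"))
  data.table::setattr(out, "class", c("insulation_track", class(out)))
  out[]
}

#' Insulation tracks over a window range
#'
#' @param m balanced `contact_matrix`.
#' @param windows vector of window sizes in bp (default 100 kb to 1 Mb in
#'   50 kb steps, clipped to multiples of the resolution).
#' @return named list of insulation tracks.
#' @export
insulation_multi <- function(m, windows = seq(100e3, 1e6, by = 50e3)) {
  windows <- windows[windows %% m$resolution == 0]
  stats::setNames(lapply(windows, function(w) insulation_score(m, w)),
                  as.character(windows))
}

#' Call TAD boundaries from an insulation track
#'
#' The delta vector at bin `i` is the mean insulation over the
#' `delta_window` bins right of `i` minus the mean over the `delta_window`
#' bins left of `i`. Boundaries are bins where delta crosses zero from
#' negative to positive around a local insulation minimum; the boundary
#' strength is the delta span across the crossing (nearest local delta
#' maximum right of the crossing minus nearest local minimum left of it),
#' so weak noise wiggles score low. Calls weaker than
#' `min_strength` are dropped. Bins near chromosome ends have undefined
#' insulation and are never called.
#'
#' @param track `insulation_track`.
#' @param delta_window half-window in bins (default 7).
#' @param min_strength minimum boundary strength (default 0.1).
#' @return data.table `boundary_set`: `chrom`, `start`, `end`, `bin`,
#'   `strength`, ordered by bin.
#' @export
call_boundaries <- function(track, delta_window = 7L, min_strength = 0.1) {
  dw <- as.integer(delta_window)
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch]
    s <- tr$score
    n <- length(s)
    if (sum(is.finite(s)) < 2L * dw) next
    delta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - dw < 1L || i + dw > n) next
      lv <- s[(i - dw):(i - 1L)]; rv <- s[(i + 1L):(i + dw)]
      if (all(is.na(lv)) || all(is.na(rv))) next
      delta[i] <- mean(rv, na.rm = TRUE) - mean(lv, na.rm = TRUE)
    }
    cross <- which(!is.na(delta[-n]) & !is.na(delta[-1]) &
                   delta[-n] < 0 & delta[-1] >= 0)
    for (cidx in cross) {
      # strength = delta span between the nearest local extremes flanking
      # the crossing (local max to the right, local min to the left)
      r <- cidx + 1L
      while (r + 1L <= n && !is.na(delta[r + 1L]) && delta[r + 1L] >= delta[r])
        r <- r + 1L
      l <- cidx
      while (l - 1L >= 1L && !is.na(delta[l - 1L]) && delta[l - 1L] <= delta[l])
        l <- l - 1L
      strength <- delta[r] - delta[l]
      if (!is.finite(strength) || strength < min_strength) next
      # place the boundary at the insulation minimum flanking the crossing
      cand <- max(1L, cidx - 1L):min(n, cidx + 2L)
      cand <- cand[is.finite(s[cand])]
      if (length(cand) == 0L) next
      bpos <- cand[which.min(s[cand])]
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = tr$start[bpos], end = tr$end[bpos],
        bin = tr$bin[bpos], strength = strength)
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), bin = integer(), strength = numeric())
  res <- unique(res, by = "bin")
  data.table::setorderv(res, "bin")
  data.table::setattr(res, "class", c("boundary_set", class(res)))
  res[]
}

#' A/B compartment eigenvector
#'
#' Per chromosome, the O/E matrix restricted to mappable bins is converted
#' to a Pearson correlation matrix between its rows; the eigenvector of the
#' largest-magnitude eigenvalue is the compartment track and its sign
#' pattern labels bins A or B. The eigenvector sign is arbitrary; by
#' default it is oriented so that label "A" has the higher mean
#' within-group O/E signal, or it can be oriented against a user reference
#' track (e.g. GC content), where "A" is the positively correlated sign.
#'
#' @param oe `contact_matrix` in `"oe"` state.
#' @param reference optional numeric per-bin reference for orientation.
#' @return data.table `compartment_track`: `chrom`, `start`, `end`, `bin`,
#'   `eigen` (unit-norm per chromosome; NA on masked bins), `label`
#'   ("A"/"B"/NA).
#' @export
compartment_eigenvector <- function(oe, reference = NULL) {
  stopifnot(oe$state == "oe")
  cid <- same_chrom_bins(oe$bins)
  eig <- rep(NA_real_, nrow(oe$bins))
  for (ch in unique(cid)) {
    sel <- which(cid == ch & oe$bins$mappable)
    if (length(sel) < 3L) next
    sub <- oe$mat[sel, sel, drop = FALSE]
    keep <- apply(sub, 1, function(r) sum(is.finite(r)) >= 3 && stats::sd(r, na.rm = TRUE) > 0)
    if (sum(keep) < 3L) {
      warning("degenerate O/E matrix on chromosome ", oe$bins$chrom[sel[1]],
              ": compartments undefined")
      next
    }
    sub <- sub[keep, keep, drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    i1 <- which.max(abs(ev$values))
    v <- ev$vectors[, i1]
    v <- v / sqrt(sum(v^2))
    idx <- sel[keep]
    # orientation
    if (!is.null(reference)) {
      r <- suppressWarnings(stats::cor(v, reference[idx]))
      if (is.finite(r) && r < 0) v <- -v
    } else {
      pos <- v > 0; neg <- v < 0
      if (any(pos) && any(neg)) {
        mpos <- mean(sub[pos, pos][upper.tri(sub[pos, pos])], na.rm = TRUE)
        mneg <- mean(sub[neg, neg][upper.tri(sub[neg, neg])], na.rm = TRUE)
        if (is.finite(mpos) && is.finite(mneg) && mneg > mpos) v <- -v
      }
    }
    eig[idx] <- v
  }
  out <- data.table::data.table(chrom = oe$bins$chrom, start = oe$bins$start,
                                end = oe$bins$end, bin = oe$bins$bin, eigen = eig)
  out[, label := data.table::fifelse(is.na(eigen), NA_character_,
                                     data.table::fifelse(eigen >= 0, "A", "B"))]
  data.table::setattr(out, "class", c("compartment_track", class(out)))
  out[]
}
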