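#' Contact matrix container
#'
#' A symmetric binned contact map: a dense numeric matrix over the global
#' bins of a `bin_table`, a per-bin bias vector (NA on unmappable bins), and
#' a normalisation state. Unmappable bins carry zero stored contacts.
#'
#' @param mat symmetric numeric matrix, one row/column per bin.
#' @param bins `bin_table` from [make_bins()].
#' @param state `"raw"`, `"balanced"` or `"oe"`.
#' @param bias per-bin balancing factors (optional).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bins, state = "raw", bias = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), nrow(mat) == nrow(bins))
  storage.mode(mat) <- "double"
  if (max(abs(mat - t(mat))) > 1e-8) stop("contact matrix must be symmetric")
  structure(list(mat = mat, bins = bins,
                 resolution = attr(bins, "bin_size"),
                 state = match.arg(state, c("raw", "balanced", "oe")),
                 bias = bias %||% rep(NA_real_, nrow(bins))),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d bins @ %s bp, state=%s, mass=%.4g\n",
              nrow(x$mat), ncol(x$mat),
              format(x$resolution, big.mark = ","), x$state,
              sum(x$mat[upper.tri(x$mat, diag = TRUE)])))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$mat)

mappable_idx <- function(m) which(m$bins$mappable)

#' Bin valid pairs into a raw contact matrix
#'
#' Each valid pair increments the cell of its two bins (and the transposed
#' mirror); the total upper-triangle-plus-diagonal mass equals the number of
#' pairs binned.
#'
#' @param pairs pair table; rows with a `filter` column are restricted to
#'   `filter == "valid"`.
#' @param bins `bin_table`.
#' @return `contact_matrix` in raw state.
#' @export
bin_pairs <- function(pairs, bins) {
  if ("filter" %in% names(pairs)) pairs <- pairs[pairs$filter == "valid"]
  N <- nrow(bins)
  b1 <- locate_bins(bins, pairs$chrom1, pairs$pos1)
  b2 <- locate_bins(bins, pairs$chrom2, pairs$pos2)
  mat <- matrix(0, N, N)
  cnt <- table(factor(pmin(b1, b2), levels = 1:N),
               factor(pmax(b1, b2), levels = 1:N))
  up <- matrix(as.numeric(cnt), N, N)
  mat <- up + t(up)
  diag(mat) <- diag(up)
  contact_matrix(mat, bins, state = "raw")
}

#' Mask low-coverage bins
#'
#' Marginal coverage is computed per bin; bins below
#' `threshold_fraction x median coverage` (median over bins with nonzero
#' coverage) are flagged unmappable and their rows/columns zeroed.
#' Zero-coverage bins are always masked.
#'
#' @param m raw `contact_matrix`.
#' @param threshold_fraction default 0.10.
#' @return `contact_matrix` with updated mappability.
#' @export
mask_low_coverage <- function(m, threshold_fraction = 0.10) {
  stopifnot(m$state == "raw")
  cov <- rowSums(m$mat)
  if (all(cov == 0)) stop("all bins empty")
  med <- stats::median(cov[cov > 0])
  bad <- cov < threshold_fraction * med
  bins <- data.table::copy(m$bins)
  bins[, mappable := mappable & !bad]
  mat <- m$mat
  mat[bad, ] <- 0
  mat[, bad] <- 0
  out <- contact_matrix(mat, bins, state = "raw")
  out$bins <- bins
  out
}

#' Mark a bias-free matrix as balanced
#'
#' Stamps a raw matrix as balanced with unit bias on mappable bins. Only
#' meaningful for matrices known to carry no coverage bias — in practice
#' the output of the bundled simulator, whose generative model has true
#' bias 1. Using ground truth instead of [kr_balance()] keeps downstream
#' statistics (O/E, TAD/loop strength) free of the marginal-flattening
#' that balancing imposes on block-enriched maps.
#'
#' @param m raw `contact_matrix`.
#' @return `contact_matrix` in balanced state, bias 1 on mappable bins.
#' @export
as_balanced <- function(m) {
  stopifnot(m$state == "raw")
  out <- m
  out$state <- "balanced"
  out$bias <- ifelse(m$bins$mappable, 1, NA_real_)
  out
}

#' Knight-Ruiz matrix balancing
#'
#' Finds positive per-bin factors `b` so that the scaled matrix
#' `b_i M_ij b_j` has equal row sums over mappable bins (normalised to mean
#' row sum 1). Uses the Knight-Ruiz inner-outer Newton iteration on the
#' mappable submatrix, falling back to Sinkhorn-Knopp iteration if the
#' Newton scheme stalls. Masked bins keep `NA` bias and zero contacts.
#'
#' @param m `contact_matrix` (raw, after [mask_low_coverage()]).
#' @param tol convergence tolerance on max row-sum deviation (default 1e-6).
#' @param max_iter maximum outer iterations (default 300).
#' @param per_chromosome balance each chromosome's intra-matrix separately
#'   (cis analyses) instead of the whole genome matrix (default FALSE:
#'   genome-wide, as required by the trans rearrangement scan).
#' @return balanced `contact_matrix` with `bias` filled on mappable bins.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 300L, per_chromosome = FALSE) {
  stopifnot(m$state == "raw")
  mat <- m$mat
  bias <- rep(NA_real_, nrow(mat))
  if (per_chromosome) {
    cid <- same_chrom_bins(m$bins)
    for (k in unique(cid)) {
      sel <- which(cid == k & m$bins$mappable)
      if (length(sel) == 0L) next
      b <- kr_core(m$mat[sel, sel, drop = FALSE], tol, max_iter,
                   label = attr(m$bins, "chroms")$names[k])
      bias[sel] <- b
      mat[sel, sel] <- m$mat[sel, sel] * tcrossprod(b)
      # zero cross-chromosome cells: per-chromosome mode is cis-only
    }
    cross <- outer(cid, cid, "!=")
    mat[cross] <- 0
  } else {
    sel <- mappable_idx(m)
    b <- kr_core(m$mat[sel, sel, drop = FALSE], tol, max_iter, label = "genome")
    bias[sel] <- b
    mat[sel, sel] <- m$mat[sel, sel] * tcrossprod(b)
  }
  out <- contact_matrix(mat, m$bins, state = "balanced", bias = bias)
  out
}

# Balance one symmetric nonnegative matrix; returns the bias vector scaled
# so that the mean row sum of diag(b) A diag(b) is 1.
kr_core <- function(A, tol, max_iter, label = "") {
  n <- nrow(A)
  if (n == 0L) return(numeric(0))
  if (n == 1L) {
    if (A[1, 1] <= 0) stopf("KR balancing failed on %s: singleton zero bin", label)
    return(1 / sqrt(A[1, 1]))
  }
  x <- kr_newton(A, tol = tol * 0.1, max_outer = max_iter)
  if (is.null(x)) x <- sinkhorn_biases(A, tol = tol * 0.1, max_iter = 5000L)
  if (is.null(x))
    stopf("KR balancing did not converge on %s within %d iterations", label, max_iter)
  # rescale: target common row sum r, mean row sum 1 is r = 1 already since
  # kr solves row sums == 1; keep a final normalisation for safety
  s <- mean(x * (A %*% x))
  x <- x / sqrt(s)
  dev <- max(abs(x * (A %*% x) - 1))
  if (dev > tol)
    stopf("KR balancing did not converge on %s (max row-sum deviation %.3g)", label, dev)
  x
}

# Knight & Ruiz (2013) algorithm 1: inner CG solves, outer Newton steps.
# Returns NULL on stall/non-convergence so the caller can fall back.
kr_newton <- function(A, tol = 1e-7, max_outer = 300L, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  rt <- tol^2
  v <- x * (A %*% x); rk <- 1 - v
  rho_km1 <- drop(crossprod(rk))
  rout <- rho_km1; rold <- rout
  MVP <- 0L; i <- 0L
  while (rout > rt) {
    i <- i + 1L
    if (i > max_outer) return(NULL)
    k <- 0L; y <- e; innertol <- max(eta^2 * rout, rt)
    rho_km1_inner <- rho_km1
    Z <- rk / v; p <- Z; rho <- drop(crossprod(rk, Z))
    while (rho_km1_inner > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v; p <- Z; rho_km1_inner <- drop(crossprod(rk, Z))
      } else {
        beta <- rho_km1_inner / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1_inner / drop(crossprod(p, w))
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1_inner
      Z <- rk / v
      rho_km1_inner <- drop(crossprod(rk, Z))
      if (k > 200L) break
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- drop(crossprod(rk))
    rout <- rho_km1
    MVP <- MVP + k + 1L
    if (MVP > 50000L) return(NULL)
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
  }
  x
}

# plain symmetric Sinkhorn-Knopp fallback: x <- x / sqrt-free alternating
# scaling toward row sums 1
sinkhorn_biases <- function(A, tol = 1e-7, max_iter = 5000L) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- drop(A %*% x) * x
    if (any(r <= 0) || any(!is.finite(r))) return(NULL)
    x <- x / sqrt(r)
    if (max(abs(drop(A %*% x) * x - 1)) < tol) return(x)
  }
  NULL
}

#' Expected contact intensity by distance
#'
#' Per chromosome, the mean balanced contact weight over all mappable bin
#' pairs at each bin distance `d`, with the count of possible mappable pairs
#' retained so that sparse distances can be recognised.
#'
#' @param m balanced `contact_matrix`.
#' @return object of class `expected_profile`: a data.table with columns
#'   `chrom`, `d` (bin distance), `expected`, `n_possible`.
#' @export
expected_by_distance <- function(m) {
  cid <- same_chrom_bins(m$bins)
  chroms <- attr(m$bins, "chroms")$names
  out <- data.table::rbindlist(lapply(unique(cid), function(k) {
    sel <- which(cid == k)
    map <- m$bins$mappable[sel]
    sub <- m$mat[sel, sel, drop = FALSE]
    n <- length(sel)
    e <- numeric(n); np <- numeric(n)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      ok <- map[i] & map[i + d]
      np[d + 1] <- sum(ok)
      e[d + 1] <- if (np[d + 1] > 0) sum(sub[cbind(i[ok], i[ok] + d)]) / np[d + 1] else NA_real_
    }
    data.table::data.table(chrom = chroms[k], d = 0:(n - 1),
                           expected = e, n_possible = np)
  }))
  data.table::setattr(out, "class", c("expected_profile", class(out)))
  out[]
}

#' Observed / expected transform
#'
#' Divides every intra-chromosomal pixel of the balanced matrix by the
#' expected value at its distance, removing the dominant distance decay.
#' Pixels on masked bins or at distances with no defined expected value
#' become `NA`; inter-chromosomal pixels are `NA` (cis-only transform).
#'
#' @param m balanced `contact_matrix`.
#' @param expected optional precomputed [expected_by_distance()] profile.
#' @return `contact_matrix` in `"oe"` state.
#' @export
oe_transform <- function(m, expected = NULL) {
  stopifnot(m$state == "balanced")
  if (is.null(expected)) expected <- expected_by_distance(m)
  cid <- same_chrom_bins(m$bins)
  chroms <- attr(m$bins, "chroms")$names
  N <- nrow(m$mat)
  oe <- matrix(NA_real_, N, N)
  for (k in unique(cid)) {
    sel <- which(cid == k)
    ev <- expected$expected[expected$chrom == chroms[k]]
    n <- length(sel)
    dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
    ed <- matrix(ev[dmat + 1], n, n)
    sub <- m$mat[sel, sel, drop = FALSE] / ed
    sub[ed <= 0 | !is.finite(ed)] <- NA_real_
    bad <- !m$bins$mappable[sel]
    sub[bad, ] <- NA_real_; sub[, bad] <- NA_real_
    oe[sel, sel] <- sub
  }
  out <- contact_matrix(ifelse(is.na(oe), 0, oe), m$bins,
                        state = "raw", bias = m$bias)
  out$mat <- oe           # keep NA semantics; constructor checked symmetry
  out$state <- "oe"
  out
}

#' Difference matrix between two samples
#'
#' Elementwise `a - b` on matching bin tables. The no-signal rule controls
#' masking: `"both"` (default) removes pixels that are zero or undefined in
#' both matrices, keeping one-sided gains/losses; `"either"` removes pixels
#' lacking signal in at least one matrix.
#'
#' @param a,b `contact_matrix` objects in the same state on identical bins.
#' @param no_signal `"both"` or `"either"`.
#' @return numeric matrix with `NA` at masked pixels.
#' @export
difference_matrix <- function(a, b, no_signal = c("both", "either")) {
  no_signal <- match.arg(no_signal)
  check_same_bins(a, b)
  d <- a$mat - b$mat
  za <- is.na(a$mat) | a$mat == 0
  zb <- is.na(b$mat) | b$mat == 0
  mask <- if (no_signal == "both") za & zb else za | zb
  d[mask] <- NA_real_
  d
}

check_same_bins <- function(a, b) {
  if (nrow(a$bins) != nrow(b$bins) || a$resolution != b$resolution ||
      !all(a$bins$chrom == b$bins$chrom) || !all(a$bins$start == b$bins$start))
    stop("bin tables differ between the two matrices")
  invisible(TRUE)
}

#' Distance-stratified correlation between two maps
#'
#' Intra-chromosomal pixels are binned by genomic distance into strata of
#' `stratum_width` bp ([0, w), [w, 2w), ...) and the Pearson correlation of
#' corresponding pixel values is computed per stratum. Strata with fewer
#' than 3 defined pixel pairs are reported `NA`.
#'
#' @param a,b `contact_matrix` objects on identical bins.
#' @param stratum_width stratum width in bp (default 250 kb).
#' @param max_distance largest genomic distance considered (default: full
#'   chromosome span).
#' @return data.table with columns `stratum_start`, `stratum_end`, `r`, `n`.
#' @export
distance_stratified_correlation <- function(a, b, stratum_width = 250e3,
                                            max_distance = Inf) {
  check_same_bins(a, b)
  res <- a$resolution
  k <- as.integer(round(stratum_width / res))   # diagonals per stratum
  if (k < 1L) stop("stratum narrower than one bin")
  cid <- same_chrom_bins(a$bins)
  N <- nrow(a$mat)
  ii <- which(upper.tri(a$mat, diag = TRUE), arr.ind = TRUE)
  same <- cid[ii[, 1]] == cid[ii[, 2]]
  ii <- ii[same, , drop = FALSE]
  d <- ii[, 2] - ii[, 1]
  keep <- d * res < max_distance & a$bins$mappable[ii[, 1]] & a$bins$mappable[ii[, 2]]
  ii <- ii[keep, , drop = FALSE]; d <- d[keep]
  stratum <- d %/% k
  va <- a$mat[ii]; vb <- b$mat[ii]
  out <- data.table::rbindlist(lapply(sort(unique(stratum)), function(s) {
    sel <- stratum == s & is.finite(va) & is.finite(vb)
    n <- sum(sel)
    r <- if (n >= 3 && stats::sd(va[sel]) > 0 && stats::sd(vb[sel]) > 0)
      stats::cor(va[sel], vb[sel]) else NA_real_
    data.table::data.table(stratum_start = s * k * res,
                           stratum_end = (s + 1) * k * res, r = r, n = n)
  }))
  out[]
}
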