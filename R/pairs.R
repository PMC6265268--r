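#' Split a read sequence at ligation junctions
#'
#' Hi-C ligation products read through a filled-in, re-ligated restriction
#' site (MboI: `GATCGATC`). Each occurrence splits the read at the junction
#' midpoint so that both sub-reads keep the half-site (`GATC`) at the split
#' point, mirroring how the aligner sees the two genomic sides of the
#' ligation.
#'
#' @param sequence read sequence (character scalar).
#' @param junction junction sequence; default the MboI filled-in product.
#' @return character vector of sub-read sequences; the input unchanged when
#'   no junction occurs; `character(0)` for an empty sequence.
#' @export
scan_ligation_junctions <- function(sequence, junction = "GATCGATC") {
  if (!nzchar(junction)) stop("junction must be non-empty")
  if (length(sequence) != 1L) stop("one sequence at a time")
  if (!nzchar(sequence)) return(character(0))
  seq <- toupper(sequence)
  hits <- gregexpr(toupper(junction), seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(sequence)
  half <- nchar(junction) %/% 2L
  cuts <- as.integer(hits) - 1L + half          # 0-based split points
  bounds <- c(0L, cuts, nchar(seq))
  substring(seq, bounds[-length(bounds)] + 1L, bounds[-1])
}

#' Build an aligned-read table
#'
#' @param read_id,chrom,pos,strand,mapq parallel vectors; `pos` is the
#'   0-based 5' mapping position.
#' @return data.table of aligned reads.
#' @export
aligned_reads <- function(read_id, chrom, pos, strand, mapq) {
  stopifnot(all(strand %in% c("+", "-")))
  data.table::data.table(read_id = as.character(read_id),
                         chrom = as.character(chrom),
                         pos = as.numeric(pos),
                         strand = as.character(strand),
                         mapq = as.integer(mapq))
}

#' Mapping-quality filter
#'
#' Removes reads with `mapq < threshold` (the threshold itself is retained;
#' multi-mappers reported at mapq 0 are always removed for any positive
#' threshold). Groups losing members fall through to the group-size rules of
#' [classify_read_groups()].
#'
#' @param reads aligned-read table.
#' @param threshold minimum retained mapping quality (default 3).
#' @return list with `reads` (retained) and `n_discarded`.
#' @export
mapq_filter <- function(reads, threshold = 3L) {
  stopifnot(threshold >= 0)
  keep <- reads$mapq >= threshold
  list(reads = reads[keep], n_discarded = sum(!keep))
}

#' Classify read groups into raw pairs
#'
#' Reads sharing one ID are grouped; split reads (junction scanning or the
#' aligner) make groups larger than two. Rules: 2 reads form a pair
#' (case i); 3 reads form a pair when two of them lie within
#' `merge_distance` bp on the same chromosome — the merged locus is
#' represented by the 5'-most of the two records — otherwise the group is
#' discarded (case ii); 4+ reads are discarded outright (case iii), as are
#' single reads left over after quality filtering.
#'
#' @param reads aligned-read table (already mapq-filtered).
#' @param chrom_order chromosome name order used for canonical pair
#'   orientation; defaults to sorted unique names.
#' @param merge_distance co-location tolerance for case ii (default 100 bp).
#' @return list with `pairs` (data.table: read_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, classification) and `n_discarded` split by
#'   reason.
#' @export
classify_read_groups <- function(reads, chrom_order = NULL,
                                 merge_distance = 100) {
  if (is.null(chrom_order)) chrom_order <- sort(unique(reads$chrom))
  reads <- data.table::as.data.table(reads)
  data.table::setorderv(reads, "read_id")
  gsize <- reads[, .N, by = read_id]
  discards <- c(unpaired = sum(gsize$N == 1L),
                case_ii_discarded = 0L,
                case_iii_discarded = sum(gsize$N >= 4L))
  # case i: exactly two reads per ID, fully vectorised
  id2 <- gsize$read_id[gsize$N == 2L]
  r2 <- reads[reads$read_id %in% id2]
  pairs2 <- if (nrow(r2)) {
    a <- r2[seq(1L, nrow(r2), by = 2L)]
    b <- r2[seq(2L, nrow(r2), by = 2L)]
    data.table::data.table(read_id = a$read_id,
                           chrom1 = a$chrom, pos1 = a$pos, strand1 = a$strand,
                           chrom2 = b$chrom, pos2 = b$pos, strand2 = b$strand,
                           classification = "case_i")
  } else NULL
  # case ii: three reads; pick the first locus pair within merge_distance
  out3 <- list()
  id3 <- gsize$read_id[gsize$N == 3L]
  if (length(id3)) {
    r3 <- reads[reads$read_id %in% id3]
    grp <- split(seq_len(nrow(r3)), r3$read_id)
    for (g in grp) {
      rows <- r3[g]
      hit <- NULL
      for (k in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
        if (rows$chrom[k[1]] == rows$chrom[k[2]] &&
            abs(rows$pos[k[1]] - rows$pos[k[2]]) <= merge_distance) { hit <- k; break }
      }
      if (is.null(hit)) {
        discards["case_ii_discarded"] <- discards["case_ii_discarded"] + 1L
        next
      }
      rep_idx <- hit[which.min(rows$pos[hit])]   # 5'-most record represents
      other <- setdiff(1:3, hit)
      out3[[length(out3) + 1L]] <- data.table::data.table(
        read_id = rows$read_id[1],
        chrom1 = rows$chrom[rep_idx], pos1 = rows$pos[rep_idx],
        strand1 = rows$strand[rep_idx],
        chrom2 = rows$chrom[other], pos2 = rows$pos[other],
        strand2 = rows$strand[other], classification = "case_ii")
    }
  }
  pairs <- data.table::rbindlist(c(list(pairs2), out3))
  if (nrow(pairs) == 0L) {
    pairs <- data.table::data.table(read_id = character(), chrom1 = character(),
      pos1 = numeric(), strand1 = character(), chrom2 = character(),
      pos2 = numeric(), strand2 = character(), classification = character())
  }
  canonicalise_pairs(pairs, chrom_order)
  list(pairs = pairs[], n_discarded = discards)
}

# canonical upper-triangle ordering: chrom1 <= chrom2 in chrom_order, then
# pos1 <= pos2 within a chromosome; strands travel with their locus
canonicalise_pairs <- function(pairs, chrom_order) {
  if (nrow(pairs) == 0L) return(invisible(pairs))
  c1 <- match(pairs$chrom1, chrom_order)
  c2 <- match(pairs$chrom2, chrom_order)
  if (anyNA(c1) || anyNA(c2)) stop("pair chromosome not in chrom_order")
  swap <- c1 > c2 | (c1 == c2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, .(chrom1, pos1, strand1)]
    pairs[swap, `:=`(chrom1 = chrom2, pos1 = pos2, strand1 = strand2)]
    pairs[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1, strand2 = tmp$strand1)]
  }
  invisible(pairs)
}

#' Assign pair loci to restriction fragments
#'
#' Each locus is mapped to the unique fragment containing it (fragments are
#' half-open, so a locus exactly at a fragment start belongs to that
#' fragment). The distance to the nearest restriction site is the distance
#' to the closer fragment edge.
#'
#' @param pairs raw-pair table from [classify_read_groups()].
#' @param fragments a `fragment_map` from [digest_genome()].
#' @return the pair table with columns `frag1`, `frag2`, `sitedist1`,
#'   `sitedist2` added.
#' @export
assign_fragments <- function(pairs, fragments) {
  loc <- function(chrom, pos) {
    res_frag <- numeric(length(chrom)); res_dist <- numeric(length(chrom))
    for (chr in unique(chrom)) {
      fr <- fragments[fragments$chrom == chr]
      if (nrow(fr) == 0L) stop("locus on unknown chromosome: ", chr)
      sel <- chrom == chr
      k <- findInterval(pos[sel], fr$start)
      if (any(k < 1L) || any(pos[sel] >= fr$end[nrow(fr)]))
        stop("locus outside chromosome ", chr)
      res_frag[sel] <- fr$frag[k]
      res_dist[sel] <- pmin(pos[sel] - fr$start[k], fr$end[k] - pos[sel])
    }
    list(frag = res_frag, dist = res_dist)
  }
  l1 <- loc(pairs$chrom1, pairs$pos1)
  l2 <- loc(pairs$chrom2, pairs$pos2)
  pairs[, `:=`(frag1 = l1$frag, frag2 = l2$frag,
               sitedist1 = l1$dist, sitedist2 = l2$dist)]
  pairs[]
}

#' Ligation-bias and fragment-level pair filters
#'
#' Flags, without removing, pairs that indicate restriction or ligation
#' artefacts: `far_from_site` when either locus lies more than
#' `site_distance_cutoff` from its nearest restriction site; `same_fragment`
#' when both loci fall on one fragment; for intra-chromosomal opposite-strand
#' pairs closer than `orientation_cutoff`, `inward_short` (unligated
#' fragment, +/- facing each other) or `outward_short` (self-ligated
#' fragment, -/+ facing away). Same-orientation pairs are never
#' orientation-flagged: they require a cut and re-ligated site between the
#' reads.
#'
#' @param pairs pair table with fragment assignments.
#' @param site_distance_cutoff bp, default 5000.
#' @param orientation_cutoff bp, default 10000 (applies strictly below).
#' @return the pair table with logical columns `same_fragment`,
#'   `far_from_site`, `inward_short`, `outward_short` added.
#' @export
filter_pairs <- function(pairs, site_distance_cutoff = 5000,
                         orientation_cutoff = 10000) {
  pairs[, same_fragment := frag1 == frag2]
  pairs[, far_from_site := sitedist1 > site_distance_cutoff |
                           sitedist2 > site_distance_cutoff]
  intra <- pairs$chrom1 == pairs$chrom2
  sep <- abs(pairs$pos2 - pairs$pos1)
  opp <- pairs$strand1 != pairs$strand2
  short <- intra & opp & sep < orientation_cutoff
  # canonical ordering guarantees pos1 <= pos2 for intra pairs
  pairs[, inward_short := short & strand1 == "+" & strand2 == "-"]
  pairs[, outward_short := short & strand1 == "-" & strand2 == "+"]
  pairs[]
}

#' Mark PCR duplicates
#'
#' A pair is a duplicate when an earlier retained pair maps to the same two
#' loci (same chromosomes and strands) within `tolerance` bp at both ends.
#' Clustering is greedy in input order: the first pair seen is the cluster
#' representative, every later matching pair is flagged.
#'
#' @param pairs canonically ordered pair table.
#' @param tolerance per-locus position tolerance in bp (default 2).
#' @return the pair table with logical column `duplicate` added.
#' @export
deduplicate <- function(pairs, tolerance = 2) {
  n <- nrow(pairs)
  dup <- logical(n)
  if (n > 0L) {
    cell <- tolerance + 1
    key0 <- paste(pairs$chrom1, pairs$chrom2, pairs$strand1, pairs$strand2, sep = "\r")
    cx <- floor(pairs$pos1 / cell); cy <- floor(pairs$pos2 / cell)
    store <- new.env(parent = emptyenv(), size = n)
    for (idx in seq_len(n)) {
      p1 <- pairs$pos1[idx]; p2 <- pairs$pos2[idx]
      found <- FALSE
      for (dx in -1:1) {
        for (dy in -1:1) {
          k <- paste0(key0[idx], "\r", cx[idx] + dx, "\r", cy[idx] + dy)
          hits <- store[[k]]
          if (!is.null(hits) &&
              any(abs(hits[1, ] - p1) <= tolerance & abs(hits[2, ] - p2) <= tolerance)) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (found) {
        dup[idx] <- TRUE
      } else {
        k <- paste0(key0[idx], "\r", cx[idx], "\r", cy[idx])
        store[[k]] <- cbind(store[[k]], c(p1, p2))
      }
    }
  }
  pairs[, duplicate := dup]
  pairs[]
}

FILTER_ORDER <- c("same_fragment", "far_from_site", "inward_short",
                  "outward_short", "duplicate")

#' First-triggering filter per pair
#'
#' Collapses the independent flag columns into one category per pair using
#' the fixed precedence same_fragment > far_from_site > inward_short >
#' outward_short > duplicate, making library statistics deterministic.
#'
#' @param pairs flagged pair table.
#' @return the table with a `filter` column ("valid" when no flag is set).
#' @export
apply_filter_precedence <- function(pairs) {
  f <- rep("valid", nrow(pairs))
  for (fl in rev(FILTER_ORDER)) {
    if (fl %in% names(pairs)) f[which(pairs[[fl]])] <- fl
  }
  pairs[, filter := f]
  pairs[]
}

#' Library pair statistics
#'
#' @param pairs pair table with a `filter` column.
#' @param n_low_mapq,n_unpaired,n_case_ii_discarded,n_case_iii_discarded
#'   upstream discard counts folded into the total.
#' @return a `pair_stats` list: total, valid, per-category counts, cis/trans
#'   counts over valid pairs, duplicate fraction.
#' @export
pair_stats <- function(pairs, n_low_mapq = 0L, n_unpaired = 0L,
                       n_case_ii_discarded = 0L, n_case_iii_discarded = 0L) {
  cat_counts <- table(factor(pairs$filter, levels = c("valid", FILTER_ORDER)))
  valid <- pairs$filter == "valid"
  cis <- sum(valid & pairs$chrom1 == pairs$chrom2)
  trans <- sum(valid) - cis
  res <- list(
    total = nrow(pairs) + n_low_mapq + n_unpaired + n_case_ii_discarded +
      n_case_iii_discarded,
    n_pairs = nrow(pairs),
    valid = sum(valid),
    low_mapq = n_low_mapq, unpaired = n_unpaired,
    case_ii_discarded = n_case_ii_discarded,
    case_iii_discarded = n_case_iii_discarded,
    filtered = as.list(cat_counts[FILTER_ORDER]),
    cis = cis, trans = trans,
    duplicate_fraction = if (nrow(pairs) > 0) sum(pairs$duplicate %||% FALSE) / nrow(pairs) else NA_real_)
  class(res) <- "pair_stats"
  res
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("<pair_stats> total %d, valid %d (cis %d / trans %d)\n",
              x$total, x$valid, x$cis, x$trans))
  f <- unlist(x$filtered)
  cat("  filtered:", paste(sprintf("%s=%d", names(f), f), collapse = ", "), "\n")
  invisible(x)
}

#' Cis/trans ratio
#'
#' Raw ratio of intra- to inter-chromosomal valid pairs, plus a
#' species-normalised version that multiplies the trans count by the ratio
#' `f` of possible intra-chromosomal to inter-chromosomal bin pairs (upper
#' triangle; the diagonal counts as intra), removing the genome-architecture
#' dependence of the raw ratio.
#'
#' @param stats a `pair_stats` object (or list with `cis` and `trans`).
#' @param bins a `bin_table` defining the possible-contact counts.
#' @return list with `raw`, `normalised`, and `f`; ratios are `NA` when
#'   `trans` is zero.
#' @export
cis_trans_ratio <- function(stats, bins) {
  nb <- table(factor(bins$chrom, levels = attr(bins, "chroms")$names))
  intra <- sum(nb * (nb + 1) / 2)
  N <- nrow(bins)
  inter <- N * (N + 1) / 2 - intra
  f <- intra / inter
  if (stats$trans == 0) return(list(raw = NA_real_, normalised = NA_real_, f = f))
  list(raw = stats$cis / stats$trans,
       normalised = stats$cis / (stats$trans * f), f = f)
}

#' Run the complete pair-processing stage
#'
#' Convenience wrapper: mapq filter, group classification, fragment
#' assignment, bias filters, duplicate marking, precedence collapse and
#' statistics.
#'
#' @param reads aligned-read table.
#' @param fragments `fragment_map`.
#' @param mapq_threshold,site_distance_cutoff,orientation_cutoff,dup_tolerance
#'   filter parameters (defaults 3, 5 kb, 10 kb, 2 bp).
#' @return list with `pairs` (flagged table) and `stats` (`pair_stats`).
#' @export
process_pairs <- function(reads, fragments, mapq_threshold = 3L,
                          site_distance_cutoff = 5000,
                          orientation_cutoff = 10000, dup_tolerance = 2) {
  mq <- mapq_filter(reads, mapq_threshold)
  cl <- classify_read_groups(mq$reads,
                             chrom_order = attr(fragments, "chroms")$names)
  pairs <- assign_fragments(cl$pairs, fragments)
  pairs <- filter_pairs(pairs, site_distance_cutoff, orientation_cutoff)
  pairs <- deduplicate(pairs, dup_tolerance)
  pairs <- apply_filter_precedence(pairs)
  stats <- pair_stats(pairs, n_low_mapq = mq$n_discarded,
                      n_unpaired = cl$n_discarded[["unpaired"]],
                      n_case_ii_discarded = cl$n_discarded[["case_ii_discarded"]],
                      n_case_iii_discarded = cl$n_discarded[["case_iii_discarded"]])
  list(pairs = pairs, stats = stats)
}
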