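#' Chromosome set
#'
#' An ordered collection of chromosome names and lengths. The order is fixed
#' and defines genome-wide bin and fragment numbering for every downstream
#' structure.
#'
#' @param lengths named numeric vector of chromosome lengths in bp; names are
#'   chromosome names, order is preserved.
#' @return an object of class `chrom_set` with fields `names` and `lengths`.
#' @export
chromosome_set <- function(lengths) {
  if (length(lengths) == 0L) stop("empty chromosome set")
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome names must be present and unique")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  structure(list(names = names(lengths), lengths = as.numeric(lengths)),
            class = "chrom_set")
}

#' @export
print.chrom_set <- function(x, ...) {
  cat(sprintf("<chrom_set> %d chromosomes, %.1f Mb total\n",
              length(x$names), sum(x$lengths) / 1e6))
  invisible(x)
}

chrom_lengths <- function(cs) stats::setNames(cs$lengths, cs$names)

#' Restriction enzyme presets
#'
#' Recognition site and cut offset for the supported enzymes. Both presets
#' are palindromic; non-palindromic enzymes are rejected because only the
#' forward strand is scanned.
#'
#' @param enzyme `"MboI"` (^GATC) or `"HindIII"` (A^AGCTT), case-insensitive;
#'   alternatively a list with elements `site` and `cut_offset`.
#' @return list with `name`, `site`, `cut_offset`, and `junction` (the
#'   filled-in re-ligated site scanned for in reads).
#' @export
enzyme_preset <- function(enzyme) {
  if (is.list(enzyme)) {
    enz <- list(name = enzyme$name %||% "custom",
                site = toupper(enzyme$site),
                cut_offset = as.integer(enzyme$cut_offset))
    enz$junction <- enzyme$junction %||% ligation_junction(enz$site, enz$cut_offset)
  } else {
    enz <- switch(tolower(enzyme),
      mboi    = list(name = "MboI", site = "GATC", cut_offset = 0L,
                     junction = "GATCGATC"),
      hindiii = list(name = "HindIII", site = "AAGCTT", cut_offset = 1L,
                     junction = "AAGCTAGCTT"),
      stop("unknown enzyme preset: ", enzyme))
  }
  check_site(enz$site, enz$cut_offset)
  enz
}

check_site <- function(site, cut_offset) {
  if (!nzchar(site)) stop("empty recognition site")
  if (grepl("[^ACGT]", site)) stop("recognition site contains invalid characters: ", site)
  if (cut_offset < 0L || cut_offset >= nchar(site))
    stop("cut offset must lie within the recognition site")
  if (site != revcomp(site))
    stop("non-palindromic recognition sites are not supported (forward-strand scan only)")
  invisible(TRUE)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Filled-in re-ligation product of a 5' overhang cut: for a site cut at
# `offset`, the junction is site[1:(L-offset)] + site[(offset+1):L].
ligation_junction <- function(site, cut_offset) {
  L <- nchar(site)
  paste0(substr(site, 1L, L - cut_offset), substr(site, cut_offset + 1L, L))
}

#' In-silico restriction digestion
#'
#' Locates every forward-strand occurrence of the recognition site and cuts at
#' `site start + cut offset`. Fragments are the intervals between consecutive
#' cut positions plus the chromosome ends, 0-based half-open, tiling each
#' chromosome exactly. Matching is case-insensitive; `N` (or any non-ACGT
#' base) never matches, so assembly gaps do not create fragments.
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @param enzyme preset name or list, see [enzyme_preset()].
#' @return a `fragment_map`: data.table with columns `chrom`, `start`, `end`,
#'   `frag` (1-based global index), and attributes `enzyme`, `chroms`.
#' @export
digest_genome <- function(sequences, enzyme = "MboI") {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) stop("empty sequence set")
  if (is.null(names(sequences))) stop("sequences must be named by chromosome")
  enz <- enzyme_preset(enzyme)
  frags <- data.table::rbindlist(lapply(names(sequences), function(chr) {
    seq <- toupper(sequences[[chr]])
    L <- nchar(seq)
    cuts <- site_cut_positions(seq, enz$site, enz$cut_offset)
    starts <- c(0, cuts)
    ends <- c(cuts, L)
    keep <- ends > starts   # cut at position 0 or L adds no fragment
    data.table::data.table(chrom = chr, start = starts[keep], end = ends[keep])
  }))
  frags[, frag := seq_len(.N)]
  cs <- chromosome_set(stats::setNames(nchar(sequences), names(sequences)))
  data.table::setattr(frags, "enzyme", enz)
  data.table::setattr(frags, "chroms", cs)
  data.table::setattr(frags, "class", c("fragment_map", class(frags)))
  frags[]
}

# 0-based cut positions of `site` in `seq` (fixed substring scan, forward
# strand). gregexpr(fixed = TRUE) finds overlapping-free matches left to
# right; restriction sites of the supported enzymes cannot self-overlap.
site_cut_positions <- function(seq, site, cut_offset) {
  hits <- gregexpr(site, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(numeric(0))
  as.numeric(hits) - 1 + cut_offset
}

#' @export
print.fragment_map <- function(x, ...) {
  enz <- attr(x, "enzyme")
  cat(sprintf("<fragment_map> %d fragments, enzyme %s (%s)\n",
              nrow(x), enz$name, enz$site))
  invisible(x)
}

#' Uniform genome bin table
#'
#' Partitions every chromosome into equidistant bins of `bin_size` bp
#' (0-based half-open; the last bin per chromosome is truncated at the
#' chromosome end). Global bin indices are 1-based and contiguous in
#' chromosome order. All bins start mappable.
#'
#' @param chroms a [chromosome_set()] or a named numeric vector of lengths.
#' @param bin_size bin width in bp.
#' @return a `bin_table`: data.table with columns `chrom`, `start`, `end`,
#'   `bin`, `mappable`; attributes `bin_size` and `chroms`.
#' @export
make_bins <- function(chroms, bin_size) {
  if (!inherits(chroms, "chrom_set")) chroms <- chromosome_set(chroms)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  bins <- data.table::rbindlist(lapply(seq_along(chroms$names), function(k) {
    L <- chroms$lengths[k]
    starts <- seq(0, L - 1, by = bin_size)
    data.table::data.table(chrom = chroms$names[k], start = starts,
                           end = pmin(starts + bin_size, L))
  }))
  bins[, bin := seq_len(.N)]
  bins[, mappable := TRUE]
  data.table::setattr(bins, "bin_size", as.numeric(bin_size))
  data.table::setattr(bins, "chroms", chroms)
  data.table::setattr(bins, "class", c("bin_table", class(bins)))
  bins[]
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> %d bins of %s bp over %d chromosomes (%d mappable)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(attr(x, "chroms")$names), sum(x$mappable)))
  invisible(x)
}

# locate the bin (1-based global index) of 0-based positions
locate_bins <- function(bins, chrom, pos) {
  cs <- attr(bins, "chroms")
  bs <- attr(bins, "bin_size")
  idx <- match(chrom, cs$names)
  if (anyNA(idx)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(idx)]), collapse = ", "))
  if (any(pos < 0 | pos >= cs$lengths[idx])) stop("position outside chromosome")
  nb <- ceiling(cs$lengths / bs)
  offset <- c(0, cumsum(nb))[idx]
  offset + floor(pos / bs) + 1
}

same_chrom_bins <- function(bins) {
  # chromosome id per bin as an integer, in chromosome-set order
  match(bins$chrom, attr(bins, "chroms")$names)
}
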