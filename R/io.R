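#' Read a FASTA file
#'
#' @param path FASTA file (multi-record, wrapped lines).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))   # first token of the header
  out
}

#' Read aligned reads from SAM text or the TSV dialect
#'
#' SAM: uses QNAME, FLAG (0x10 = reverse strand, 0x4 = unmapped skipped),
#' RNAME, POS (converted to 0-based) and MAPQ; header lines ignored.
#' TSV dialect: columns `read_id`, `chrom`, `pos` (0-based), `strand`,
#' `mapq`, with a header row.
#'
#' @param path input file.
#' @param format `"sam"` or `"tsv"`; guessed from the extension by default.
#' @return aligned-read data.table.
#' @export
read_aligned_reads <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  if (format == "sam") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines) == 0L) return(aligned_reads(character(), character(),
                                                  numeric(), character(), integer()))
    f <- data.table::fread(text = lines, header = FALSE, sep = "\t", fill = TRUE)
    flag <- as.integer(f[[2]])
    keep <- bitwAnd(flag, 4L) == 0L & f[[3]] != "*"
    f <- f[keep]; flag <- flag[keep]
    aligned_reads(f[[1]], f[[3]], as.numeric(f[[4]]) - 1,
                  ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"), as.integer(f[[5]]))
  } else {
    f <- data.table::fread(path, sep = "\t")
    aligned_reads(f$read_id, f$chrom, f$pos, f$strand, f$mapq)
  }
}

PAIRS_COLS <- c("readID", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")

#' Write pairs in the .pairs text dialect
#'
#' Header lines start with `#`; columns readID chrom1 pos1 chrom2 pos2
#' strand1 strand2, positions 1-based, upper-triangle ordering (chrom1 <=
#' chrom2 in the stated chromosome order) enforced on write. The only
#' place in the package where coordinates are 1-based.
#'
#' @param pairs pair table (0-based internal positions).
#' @param path output path.
#' @param chrom_order chromosome order for canonicalisation; defaults to
#'   sorted names.
#' @export
write_pairs <- function(pairs, path, chrom_order = NULL) {
  pairs <- data.table::as.data.table(pairs)
  if (is.null(chrom_order)) chrom_order <- sort(unique(c(pairs$chrom1, pairs$chrom2)))
  canonicalise_pairs(pairs, chrom_order)
  header <- c("## pairs format v1.0",
              paste0("#chromorder: ", paste(chrom_order, collapse = " ")),
              paste0("#columns: ", paste(PAIRS_COLS, collapse = " ")))
  body <- pairs[, .(readID = read_id, chrom1, pos1 = as.integer(pos1 + 1),
                    chrom2, pos2 = as.integer(pos2 + 1), strand1, strand2)]
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a .pairs text file
#'
#' @param path input path.
#' @return pair table with 0-based positions.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L)
    return(data.table::data.table(read_id = character(), chrom1 = character(),
      pos1 = numeric(), strand1 = character(), chrom2 = character(),
      pos2 = numeric(), strand2 = character()))
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 7L))
    stopf("malformed .pairs line %d: expected 7 columns, got %d",
          which(nf != 7L)[1] + sum(startsWith(lines, "#")), nf[nf != 7L][1])
  f <- data.table::fread(text = body, header = FALSE, sep = "\t",
    col.names = PAIRS_COLS)
  data.table::data.table(read_id = as.character(f$readID),
    chrom1 = f$chrom1, pos1 = as.numeric(f$pos1) - 1, strand1 = f$strand1,
    chrom2 = f$chrom2, pos2 = as.numeric(f$pos2) - 1, strand2 = f$strand2)
}

#' Write a contact matrix as bins BED + COO triplets
#'
#' Bins go to a BED file (0-based half-open) with bin index and a
#' mappability column; nonzero upper-triangle pixels go to a TSV of
#' `bin_i`, `bin_j`, `weight` with `bin_i <= bin_j` (1-based global bin
#' indices).
#'
#' @param m `contact_matrix`.
#' @param path_bins,path_coo output paths.
#' @export
write_matrix <- function(m, path_bins, path_coo) {
  bins <- m$bins[, .(chrom, start = as.integer(start), end = as.integer(end),
                     bin, mappable = as.integer(mappable))]
  data.table::fwrite(bins, path_bins, sep = "\t", col.names = TRUE)
  up <- which(upper.tri(m$mat, diag = TRUE) & m$mat != 0 & is.finite(m$mat),
              arr.ind = TRUE)
  coo <- data.table::data.table(bin_i = up[, 1], bin_j = up[, 2],
                                weight = m$mat[up])
  data.table::setorderv(coo, c("bin_i", "bin_j"))
  data.table::fwrite(coo, path_coo, sep = "\t", col.names = TRUE)
  invisible(path_coo)
}

#' Read a contact matrix from bins BED + COO triplets
#'
#' @param path_bins,path_coo input paths (see [write_matrix()]).
#' @param state normalisation state to stamp on the result.
#' @return `contact_matrix`.
#' @export
read_matrix <- function(path_bins, path_coo, state = "raw") {
  bt <- data.table::fread(path_bins, sep = "\t")
  chroms <- chromosome_set(vapply(split(bt$end, bt$chrom)[unique(bt$chrom)],
                                  max, numeric(1)))
  sizes <- bt$end - bt$start
  bins <- make_bins(chroms, max(sizes))
  if (nrow(bins) != nrow(bt)) stop("bin table is not a uniform binning")
  bins[, mappable := as.logical(bt$mappable)]
  coo <- data.table::fread(path_coo, sep = "\t")
  if (nrow(coo) && any(coo$bin_i > coo$bin_j))
    stop("COO file must be upper-triangle (bin_i <= bin_j)")
  if (nrow(coo) && (max(coo$bin_j) > nrow(bins) || min(coo$bin_i) < 1L))
    stop("COO bin index outside bin table")
  mat <- matrix(0, nrow(bins), nrow(bins))
  if (nrow(coo)) {
    mat[cbind(coo$bin_i, coo$bin_j)] <- coo$weight
    mat[cbind(coo$bin_j, coo$bin_i)] <- coo$weight
  }
  contact_matrix(mat, bins, state = state)
}

#' Write intervals as BED
#'
#' @param dt data.frame with `chrom`, `start`, `end` and optionally a score
#'   column named by `score_col`.
#' @param path output path.
#' @param score_col optional column written into the BED score field.
#' @export
write_bed <- function(dt, path, score_col = NULL) {
  out <- data.table::data.table(chrom = dt$chrom,
                                start = as.integer(dt$start),
                                end = as.integer(dt$end))
  if (!is.null(score_col)) {
    out[, name := "."]
    out[, score := dt[[score_col]]]
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first 3-5 columns)
#' @param path input path.
#' @return data.table with `chrom`, `start`, `end` (+ `name`, `score`).
#' @export
read_bed <- function(path) {
  f <- data.table::fread(path, sep = "\t", header = FALSE)
  nm <- c("chrom", "start", "end", "name", "score")[seq_len(min(ncol(f), 5L))]
  data.table::setnames(f, seq_along(nm), nm)
  f[]
}

#' Write a bedGraph track
#'
#' @param dt data.frame with `chrom`, `start`, `end` and a value column.
#' @param path output path.
#' @param value_col name of the value column (default `"score"`).
#' @export
write_bedgraph <- function(dt, path, value_col = "score") {
  out <- data.table::data.table(chrom = dt$chrom,
                                start = as.integer(dt$start),
                                end = as.integer(dt$end),
                                value = dt[[value_col]])
  out <- out[is.finite(out$value)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write anchor pairs / calls as BEDPE
#'
#' @param dt data.frame with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` plus any extra columns (appended after the six).
#' @param path output path.
#' @export
write_bedpe <- function(dt, path) {
  core <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra <- setdiff(names(dt), core)
  out <- data.table::as.data.table(dt)[, c(core, extra), with = FALSE]
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#' @param path input path.
#' @return data.table.
#' @export
read_bedpe <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Write an expected-by-distance profile as TSV
#' @param profile [expected_by_distance()] output.
#' @param path output path.
#' @param resolution bin size in bp used to report `distance_bp`.
#' @export
write_expected <- function(profile, path, resolution) {
  out <- data.table::data.table(chrom = profile$chrom,
                                distance_bp = profile$d * resolution,
                                expected = profile$expected,
                                n_possible = profile$n_possible)
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
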