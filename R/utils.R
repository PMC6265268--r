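`%||%` <- function(a, b) if (is.null(a)) b else a

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "frag", "bin", "mappable", "chrom", "start", "end", "chrom1", "chrom2",
  "pos1", "pos2", "strand1", "strand2", "read_id", "mapq", "frag1", "frag2",
  "sitedist1", "sitedist2", "filter", "i", "j", "weight", "count", "score",
  "strength", "viewpoint", "target", "value", ".", "name", "same_fragment",
  "far_from_site", "inward_short", "outward_short", "duplicate", "n_merged",
  "label", "eigen", "bin1", "bin2", "start1", "end1", "start2", "end2",
  "pos", "strand", "readID", ".N", ".I", "seed"))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

msg <- function(...) message("[lowhic] ", sprintf(...))
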