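# Interval plumbing shared by the parser, the UR extractor and the
# generator. Convention: 0-based half-open [start, end); an interval with
# wraps = TRUE on a circular chromosome of length L covers [start, L) U [0, end).

.emptyIntervals <- function() {
  .interval(integer(), integer(), logical())
}

# cheap data.frame constructor for the hot parsing path
.interval <- function(start, end, wraps = FALSE) {
  start <- as.integer(start)
  structure(list(start = start, end = as.integer(end),
                 wraps = rep_len(as.logical(wraps), length(start))),
            class = "data.frame",
            row.names = if (length(start)) seq_along(start) else integer())
}

.intervalWidth <- function(iv, L) {
  ifelse(iv$wraps, (L - iv$start) + iv$end, iv$end - iv$start)
}

# Linearize to IRanges (1-based closed), splitting wrapped intervals in two.
.asIRanges <- function(iv, L) {
  if (nrow(iv) == 0L) return(IRanges::IRanges())
  starts <- ends <- integer(0)
  for (i in seq_len(nrow(iv))) {
    if (iv$wraps[i]) {
      starts <- c(starts, iv$start[i] + 1L, 1L)
      ends   <- c(ends, L, iv$end[i])
    } else {
      starts <- c(starts, iv$start[i] + 1L)
      ends   <- c(ends, iv$end[i])
    }
  }
  IRanges::IRanges(start = starts, end = ends)
}

# Extract the 5'->3' nucleotide string of a feature from the plus strand
# (character in, character out; the hot path for CDS and UR slicing).
# Intervals are concatenated in annotation order; minus-strand features are
# reverse-complemented after concatenation (GenBank complement(join(...))
# semantics).
.featureSeqChr <- function(seqChr, iv, strand, L = nchar(seqChr)) {
  parts <- character()
  for (i in seq_len(nrow(iv))) {
    if (iv$wraps[i]) {
      parts <- c(parts, substring(seqChr, iv$start[i] + 1L, L),
                 substring(seqChr, 1L, iv$end[i]))
    } else {
      parts <- c(parts, substring(seqChr, iv$start[i] + 1L, iv$end[i]))
    }
  }
  s <- paste(parts, collapse = "")
  if (strand == "-") .revcompChr(s) else s
}

.revcompChr <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

.featureSeq <- function(sequence, iv, strand, L = length(sequence)) {
  Biostrings::DNAString(.featureSeqChr(as.character(sequence), iv, strand, L))
}

# Serialize an interval table to a span key (used for deduplication).
.spanKey <- function(iv, strand) {
  paste0(strand, "|", paste(iv$start, iv$end, as.integer(iv$wraps),
                            sep = ":", collapse = ","))
}

.collapseFlags <- function(flags) {
  if (length(flags) == 0L) "" else paste(flags, collapse = ",")
}
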