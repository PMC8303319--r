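#' Nucleotide skews and A+T content
#'
#' Compositional descriptors of the deposited plus strand. AT-skew is
#' \eqn{(A - T)/(A + T)} and GC-skew \eqn{(G - C)/(G + C)}, so an excess of
#' A (resp. G) on the plus strand gives a positive value; an excess of C
#' gives a negative GC-skew. A+T content is \eqn{100 (A + T)/(A + C + G +
#' T)} in percent. Ambiguity codes are excluded from both numerator and
#' denominator; a zero denominator yields \code{NA}, never an error.
#'
#' @param sequence A \link[Biostrings]{DNAString} or nucleotide string.
#' @return A numeric scalar (\code{NA} when undefined).
#' @examples
#' atSkew("AATC")   # 1/3
#' gcSkew("GGGC")   # 0.5
#' atSkew("GGCC")   # NA: no A or T
#' @export
atSkew <- function(sequence) {
  n <- .baseCounts(sequence)
  if (n["A"] + n["T"] == 0) return(NA_real_)
  unname((n["A"] - n["T"]) / (n["A"] + n["T"]))
}

#' @rdname atSkew
#' @export
gcSkew <- function(sequence) {
  n <- .baseCounts(sequence)
  if (n["G"] + n["C"] == 0) return(NA_real_)
  unname((n["G"] - n["C"]) / (n["G"] + n["C"]))
}

#' @rdname atSkew
#' @export
atContent <- function(sequence) {
  n <- .baseCounts(sequence)
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  unname(100 * (n["A"] + n["T"]) / tot)
}

.baseCounts <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  af <- Biostrings::alphabetFrequency(sequence)
  af[c("A", "C", "G", "T")]
}

#' Strand-usage skew
#'
#' Asymmetry of annotated gene counts between the two strands:
#' \eqn{|n_+ - n_-| / (n_+ + n_-)} over the record's gene set (only the
#' absolute value is used as a genome descriptor). \code{NA} when no genes
#' are annotated.
#'
#' @param x A \linkS4class{GenomeRecord}, or a character vector of strands
#'   (\code{"+"}/\code{"-"}), one per gene.
#' @return Numeric in \code{[0, 1]}, or \code{NA}.
#' @export
strandUsageSkew <- function(x) {
  strands <- if (is(x, "GenomeRecord")) geneSet(x)$strand else x
  if (length(strands) == 0L) return(NA_real_)
  np <- sum(strands == "+"); nm <- sum(strands == "-")
  abs(np - nm) / (np + nm)
}

#' Unassigned (intergenic) regions
#'
#' Maximal intervals covered by no gene-set feature. Overlapping and
#' adjacent feature spans are merged before taking complements; on a
#' circular record the two gaps flanking the origin merge into a single
#' origin-spanning region. Requires at least one annotated gene
#' (otherwise \code{NULL}: the UR metrics are not computable).
#'
#' @param record A \linkS4class{GenomeRecord}.
#' @return data.frame with columns \code{start}, \code{end}, \code{wraps},
#'   \code{width} (0-based half-open coordinates), or \code{NULL} when the
#'   gene set is empty. Zero rows when genes tile the whole sequence.
#' @export
unassignedRegions <- function(record) {
  stopifnot(is(record, "GenomeRecord"))
  gs <- geneSet(record)
  if (nrow(gs) == 0L) return(NULL)
  L <- length(record@sequence)
  cov <- IRanges::reduce(do.call(c, lapply(gs$intervals, .asIRanges, L = L)))
  gaps <- IRanges::gaps(cov, start = 1L, end = L)
  iv <- if (length(gaps) == 0L) .emptyIntervals() else
    .interval(IRanges::start(gaps) - 1L, IRanges::end(gaps), FALSE)
  if (record@topology == "circular" && nrow(iv) >= 2L) {
    first <- which(iv$start == 0L)
    last <- which(iv$end == L)
    if (length(first) == 1L && length(last) == 1L && first != last) {
      merged <- .interval(iv$start[last], iv$end[first], TRUE)
      iv <- rbind(iv[-c(first, last), ], merged)
      rownames(iv) <- NULL
    }
  }
  iv$width <- .intervalWidth(iv, L)
  iv
}

#' Codon adaptation index (self-referential)
#'
#' Measures how unbalanced codon usage is within synonymous families.
#' Codon counts are pooled over all in-frame codons of all extracted CDSs
#' (trailing partial codons and codons containing ambiguity codes are
#' dropped). The relative adaptiveness of codon \eqn{c} is \eqn{w(c) =
#' n(c) / \max_{c' \in fam(c)} n(c')} within its synonymous family under
#' the record's genetic code, and CAI is the geometric mean of \eqn{w}
#' over all counted codons. Stop codons and single-codon families (which
#' carry no usage information) are excluded. The reference set is the
#' record's own CDSs, so the index is comparable across arbitrary taxa
#' without external reference tables.
#'
#' The genetic code is resolved in the order: CDS \code{/transl_table}
#' qualifier (modal value), record-level code, standard code (id 1).
#'
#' @param record A \linkS4class{GenomeRecord}.
#' @return Numeric in \code{(0, 1]}, or \code{NA} when the record has no
#'   CDS or no eligible codons.
#' @export
cai <- function(record) {
  stopifnot(is(record, "GenomeRecord"))
  cds <- .extractCDSChr(record)
  if (length(cds) == 0L) return(NA_real_)
  codons <- unlist(lapply(cds, .splitCodons), use.names = FALSE)
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  if (!length(codons)) return(NA_real_)
  codeId <- record@geneticCode
  if (is.na(codeId) || codeId < 1L) codeId <- 1L
  gcode <- Biostrings::getGeneticCode(as.character(codeId))
  caiFromCounts(table(codons), gcode)
}

#' @rdname cai
#' @param counts Named table/vector of codon counts.
#' @param gcode Named character vector mapping codons to amino acids (as
#'   returned by \code{\link[Biostrings]{getGeneticCode}}).
#' @export
caiFromCounts <- function(counts, gcode) {
  counts <- counts[counts > 0]
  fam <- split(names(gcode), gcode)
  fam <- fam[names(fam) != "*"]
  fam <- fam[lengths(fam) > 1L]
  eligible <- unlist(fam, use.names = FALSE)
  logSum <- 0; nTot <- 0
  for (codons in fam) {
    n <- as.numeric(counts[codons])
    n[is.na(n)] <- 0
    if (sum(n) == 0) next
    w <- n / max(n)
    use <- n > 0
    logSum <- logSum + sum(n[use] * log(w[use]))
    nTot <- nTot + sum(n)
  }
  if (nTot == 0) return(NA_real_)
  exp(logSum / nTot)
}

.splitCodons <- function(s) {
  nc <- nchar(s)
  if (nc < 3L) return(character())
  n <- nc %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Compute the eleven per-genome variables
#'
#' Assembles the full metric row for a record: length, topology, gene
#' count, |strand-usage skew|, A+T content, AT-skew, GC-skew, CAI, and the
#' percentage, A+T content and median length of unassigned regions. A
#' variable is \code{NA} exactly when its computability constraint fails
#' (no annotated gene: strand-usage skew and the UR metrics; no CDS: CAI);
#' values are never imputed.
#'
#' @param record A \linkS4class{GenomeRecord}.
#' @return One-row data.frame with columns \code{accession},
#'   \code{length_bp}, \code{topology}, \code{n_genes}, \code{su_skew},
#'   \code{at_content}, \code{at_skew}, \code{gc_skew}, \code{cai},
#'   \code{ur_percent}, \code{ur_at_content}, \code{ur_median_length} and
#'   \code{flags} (comma-joined \code{\link{validateRecord}} codes).
#' @examples
#' gb <- generateGenome(genomeSpec(seed = 7))
#' rec <- parseGenBank(gb$text, text = TRUE)[[1]]
#' computeMetrics(rec)
#' @export
computeMetrics <- function(record) {
  stopifnot(is(record, "GenomeRecord"))
  flags <- validateRecord(record)
  L <- length(record@sequence)
  gs <- geneSet(record)
  urs <- unassignedRegions(record)
  urPercent <- urAt <- urMed <- NA_real_
  if (!is.null(urs)) {
    urPercent <- 100 * sum(urs$width) / L
    if (nrow(urs) > 0L) {
      urMed <- stats::median(urs$width)
      urAt <- atContent(.featureSeqChr(as.character(record@sequence), urs, "+"))
    }
  }
  data.frame(
    accession = record@accession,
    length_bp = L,
    topology = record@topology,
    n_genes = nrow(gs),
    su_skew = strandUsageSkew(record),
    at_content = atContent(record@sequence),
    at_skew = atSkew(record@sequence),
    gc_skew = gcSkew(record@sequence),
    cai = cai(record),
    ur_percent = urPercent,
    ur_at_content = urAt,
    ur_median_length = urMed,
    flags = .collapseFlags(flags),
    stringsAsFactors = FALSE
  )
}
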