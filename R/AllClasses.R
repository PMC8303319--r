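#' @include AllGenerics.R
NULL

#' GenomeRecord: one parsed mitochondrial chromosome
#'
#' Internal data model for a single GenBank entry: the deposited plus-strand
#' sequence, the LOCUS topology, the annotated features with resolved
#' coordinates, the ORGANISM lineage and the genetic code.
#'
#' Feature coordinates are stored 0-based half-open (\code{[start, end)});
#' GenBank's 1-based inclusive locations are converted on ingestion. An
#' interval with \code{wraps = TRUE} covers \code{[start, L) U [0, end)} on a
#' circular chromosome of length \code{L} (an origin-spanning feature).
#'
#' @slot accession Accession number (LOCUS name if ACCESSION absent).
#' @slot definition DEFINITION line of the record.
#' @slot organism Organism name from the SOURCE/ORGANISM block.
#' @slot sequence \link[Biostrings]{DNAString}, the deposited plus strand.
#' @slot topology \code{"circular"} or \code{"linear"}.
#' @slot topologyKnown \code{FALSE} when the LOCUS line carried no topology
#'   token and linear was assumed.
#' @slot features \link[S4Vectors]{DataFrame} with columns \code{kind}
#'   (gene/CDS/tRNA/rRNA/other), \code{name}, \code{strand} (\code{"+"} or
#'   \code{"-"}), \code{transl_table} (integer, NA when absent),
#'   \code{partial} (logical) and \code{intervals}, a list column of
#'   data.frames with columns \code{start}, \code{end}, \code{wraps}.
#' @slot lineage Character vector of taxon names, root first; may be empty.
#' @slot geneticCode NCBI translation-table id (modal CDS
#'   \code{/transl_table}, 1 when no CDS declares one).
#'
#' @seealso \code{\link{parseGenBank}}, \code{\link{computeMetrics}}
#' @export
setClass("GenomeRecord",
  representation(
    accession     = "character",
    definition    = "character",
    organism      = "character",
    sequence      = "DNAString",
    topology      = "character",
    topologyKnown = "logical",
    features      = "DataFrame",
    lineage       = "character",
    geneticCode   = "integer"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@accession) != 1L) msg <- c(msg, "accession must be length 1")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  ft <- object@features
  need <- c("kind", "name", "strand", "transl_table", "partial", "intervals")
  if (!all(need %in% colnames(ft)))
    msg <- c(msg, paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(ft) > 0L) {
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
    L <- length(object@sequence)
    ok <- vapply(ft$intervals, function(iv) {
      is.data.frame(iv) && nrow(iv) >= 1L &&
        all(iv$start >= 0L) && all(iv$end <= L) &&
        all(ifelse(iv$wraps, iv$start < L & iv$end >= 1L, iv$start < iv$end))
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "malformed feature intervals")
    if (object@topology == "linear" &&
        any(vapply(ft$intervals, function(iv) any(iv$wraps), logical(1))))
      msg <- c(msg, "wraps_origin intervals are only valid on circular records")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeRecord-accessors
#' @aliases accession,GenomeRecord-method
setMethod("accession", "GenomeRecord", function(x) x@accession)

#' @rdname GenomeRecord-accessors
setMethod("definition", "GenomeRecord", function(x) x@definition)

#' @rdname GenomeRecord-accessors
setMethod("organismName", "GenomeRecord", function(x) x@organism)

#' @rdname GenomeRecord-accessors
setMethod("recordSeq", "GenomeRecord", function(x) x@sequence)

#' @rdname GenomeRecord-accessors
setMethod("topology", "GenomeRecord", function(x) x@topology)

#' @rdname GenomeRecord-accessors
setMethod("seqLength", "GenomeRecord", function(x) length(x@sequence))

#' @rdname GenomeRecord-accessors
setMethod("features", "GenomeRecord", function(x) x@features)

#' @rdname GenomeRecord-accessors
setMethod("lineage", "GenomeRecord", function(x) x@lineage)

#' @rdname GenomeRecord-accessors
setMethod("geneticCode", "GenomeRecord", function(x) x@geneticCode)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord:", object@accession, "\n")
  cat(" ", length(object@sequence), "bp", object@topology,
      if (!object@topologyKnown) "(assumed)" else "", "\n")
  cat("  features:", nrow(object@features),
      sprintf("(%d gene, %d CDS, %d tRNA, %d rRNA)",
              sum(object@features$kind == "gene"),
              sum(object@features$kind == "CDS"),
              sum(object@features$kind == "tRNA"),
              sum(object@features$kind == "rRNA")), "\n")
  cat("  organism:", object@organism, "| genetic code:", object@geneticCode, "\n")
  if (length(object@lineage))
    cat("  lineage:", paste(utils::head(object@lineage, 4), collapse = "; "),
        if (length(object@lineage) > 4) "..." else "", "\n")
})

#' PortraitTable: the assembled per-record matrix
#'
#' A \link[S4Vectors]{DFrame} subclass holding one row per accepted record:
#' identifiers, the eleven per-genome variables, taxonomy placements, the
#' genetic code and ecology placeholder columns. See
#' \code{\link{portraitColumns}} for the versioned column schema.
#'
#' @seealso \code{\link{buildPortraitTable}}, \code{\link{writePortraitCSV}}
#' @export
setClass("PortraitTable", contains = "DFrame")

setValidity("PortraitTable", function(object) {
  miss <- setdiff(portraitColumns(), colnames(object))
  if (length(miss))
    paste("missing portrait columns:", paste(miss, collapse = ", "))
  else TRUE
})

#' CorrelationMatrix: pairwise Spearman correlations
#'
#' Symmetric matrices of tie-corrected Spearman rank correlations, two-sided
#' p-values (t approximation) and pairwise-complete sample sizes over a set
#' of portrait variables. Cells with fewer than 3 complete pairs or a
#' constant variable are NA. No multiple-testing correction is applied;
#' both rho and p are always reported so any threshold can be applied.
#'
#' @slot variables Variable names (row/column order of the matrices).
#' @slot rho Spearman rho matrix, diagonal 1.
#' @slot p Two-sided p-value matrix, diagonal NA.
#' @slot n Pairwise-complete observation counts.
#' @slot alpha Significance threshold used by \code{significant()}.
#' @seealso \code{\link{spearmanMatrix}}
#' @export
setClass("CorrelationMatrix",
  representation(variables = "character", rho = "matrix", p = "matrix",
                 n = "matrix", alpha = "numeric")
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  k <- length(object@variables)
  for (s in c("rho", "p", "n")) {
    m <- slot(object, s)
    if (!all(dim(m) == c(k, k))) msg <- c(msg, paste(s, "has wrong dimensions"))
  }
  r <- object@rho
  if (any(abs(r[!is.na(r)]) > 1 + 1e-12)) msg <- c(msg, "rho outside [-1, 1]")
  if (!isTRUE(all.equal(r, t(r)))) msg <- c(msg, "rho not symmetric")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a scalar in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix over", length(object@variables), "variables",
      sprintf("(alpha = %g)\n", object@alpha))
  r <- round(object@rho, 2)
  sig <- !is.na(object@p) & object@p < object@alpha
  out <- matrix(ifelse(is.na(r), ".", paste0(format(r), ifelse(sig, "*", " "))),
                nrow = nrow(r), dimnames = dimnames(r))
  print(out, quote = FALSE)
  cat("(* p <", object@alpha, "; two-sided t approximation, pairwise-complete)\n")
})

#' Significant cells of a CorrelationMatrix
#'
#' @param x A \linkS4class{CorrelationMatrix}.
#' @return Logical matrix: \code{TRUE} where \code{p < alpha}.
#' @export
significant <- function(x) {
  stopifnot(is(x, "CorrelationMatrix"))
  !is.na(x@p) & x@p < x@alpha
}

#' Rho / p-value / n accessors for CorrelationMatrix
#'
#' @param x A \linkS4class{CorrelationMatrix}.
#' @return A numeric matrix.
#' @export
corRho <- function(x) { stopifnot(is(x, "CorrelationMatrix")); x@rho }

#' @rdname corRho
#' @export
corP <- function(x) { stopifnot(is(x, "CorrelationMatrix")); x@p }

#' @rdname corRho
#' @export
corN <- function(x) { stopifnot(is(x, "CorrelationMatrix")); x@n }

#' AuditReport: strand-annotation convention diagnostics
#'
#' Per-record gene-strand counts, the strand of cox1, the majority strand,
#' and a convention class; plus the partition of the cohort into convention
#' classes (overall and per group when a grouping was supplied).
#'
#' Convention classes: \code{cox1_on_plus_minority} (cox1 on plus, plus is
#' the minority strand), \code{majority_on_plus} (most genes on plus, cox1
#' on minus), \code{consistent} (cox1 sits on the majority strand),
#' \code{indeterminate} (no cox1, ambiguous cox1 strand, or a strand tie).
#'
#' @slot records data.frame with columns accession, group, n_plus, n_minus,
#'   cox1_strand, majority_strand, convention.
#' @slot partition data.frame of convention counts (per group when grouped).
#' @seealso \code{\link{strandConventionAudit}}
#' @export
setClass("AuditReport",
  representation(records = "data.frame", partition = "data.frame")
)

setValidity("AuditReport", function(object) {
  msg <- character()
  need <- c("accession", "group", "n_plus", "n_minus", "cox1_strand",
            "majority_strand", "convention")
  if (!all(need %in% colnames(object@records)))
    msg <- c(msg, "records is missing required columns")
  if (sum(object@partition$count) != nrow(object@records))
    msg <- c(msg, "partition counts must sum to the cohort size")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AuditReport", function(object) {
  cat("AuditReport:", nrow(object@records), "records\n")
  print(object@partition, row.names = FALSE)
})

#' @rdname AuditReport-class
#' @param x An \linkS4class{AuditReport}.
#' @return \code{auditRecords}: the per-record data.frame;
#'   \code{auditPartition}: convention counts.
#' @export
auditRecords <- function(x) { stopifnot(is(x, "AuditReport")); x@records }

#' @rdname AuditReport-class
#' @export
auditPartition <- function(x) { stopifnot(is(x, "AuditReport")); x@partition }
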