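#' Accessors for GenomeRecord objects
#'
#' @param x A \linkS4class{GenomeRecord}.
#' @return \code{accession}, \code{definition}, \code{organismName} and
#'   \code{topology} return a character scalar; \code{recordSeq} a
#'   \link[Biostrings]{DNAString}; \code{seqLength} an integer;
#'   \code{features} a \link[S4Vectors]{DataFrame} with one row per
#'   annotated feature; \code{lineage} a character vector of taxon names
#'   from root to tip; \code{geneticCode} the NCBI translation-table id.
#' @name GenomeRecord-accessors
#' @rdname GenomeRecord-accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("definition", function(x) standardGeneric("definition"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("organismName", function(x) standardGeneric("organismName"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("recordSeq", function(x) standardGeneric("recordSeq"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("geneticCode", function(x) standardGeneric("geneticCode"))
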