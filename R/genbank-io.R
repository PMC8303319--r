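#' Parse GenBank flat-file records
#'
#' Reads one or more records from a GenBank flat file into
#' \linkS4class{GenomeRecord} objects. Feature locations (including
#' \code{complement}, \code{join}/\code{order} and origin-spanning joins on
#' circular records) are resolved into ordered 0-based half-open intervals;
#' a join whose consecutive segments abut across the origin of a circular
#' record is collapsed into a single interval with \code{wraps = TRUE}.
#'
#' Malformed records (no sequence, unreadable LOCUS) are skipped with a
#' diagnostic rather than raising an error, mirroring how large-scale
#' mining pipelines discard unparseable entries; individual features whose
#' locations cannot be resolved are dropped the same way. Diagnostics are
#' attached to the result as \code{attr(, "diagnostics")}, a data.frame
#' with columns \code{record}, \code{unit} and \code{reason}.
#'
#' @param input Path to a GenBank flat file, or a character vector of its
#'   lines (use \code{text = TRUE} to force the latter for a single string).
#' @param text If \code{TRUE}, \code{input} is treated as file content, not
#'   a path.
#' @return A named list of \linkS4class{GenomeRecord} (names = accessions),
#'   with a \code{"diagnostics"} attribute.
#' @examples
#' gb <- generateGenome(genomeSpec(seed = 1))
#' rec <- parseGenBank(gb$text, text = TRUE)[[1]]
#' rec
#' @export
parseGenBank <- function(input, text = FALSE) {
  lines <- if (text || length(input) > 1L || grepl("\n", input[1], fixed = TRUE)) {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(input, warn = FALSE)
  }
  # split on record terminators
  term <- which(trimws(lines) == "//")
  starts <- c(1L, utils::head(term, -1L) + 1L)
  if (length(term) == 0L) { starts <- 1L; term <- length(lines) }
  records <- list()
  diags <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:term[k]]
    chunk <- chunk[nzchar(trimws(chunk)) & trimws(chunk) != "//"]
    if (!length(chunk)) next
    rec <- tryCatch(.parseOneRecord(chunk), error = function(e) e)
    if (is(rec, "error")) {
      diags[[length(diags) + 1L]] <- data.frame(
        record = paste0("record#", k), unit = "record",
        reason = conditionMessage(rec))
      next
    }
    if (nrow(rec$featureDiags))
      diags[[length(diags) + 1L]] <- rec$featureDiags
    records[[rec$record@accession]] <- rec$record
  }
  diags <- if (length(diags)) do.call(rbind, diags) else
    data.frame(record = character(), unit = character(), reason = character())
  structure(records, diagnostics = diags)
}

.parseOneRecord <- function(chunk) {
  locusLine <- grep("^LOCUS", chunk, value = TRUE)
  if (!length(locusLine)) stop("no LOCUS line")
  toks <- strsplit(trimws(locusLine[1]), "[[:space:]]+")[[1]]
  locusName <- if (length(toks) >= 2) toks[2] else "unknown"
  bpPos <- match("bp", toks)
  if (is.na(bpPos) || bpPos < 3) stop("LOCUS line lacks a 'bp' length")
  declaredLen <- suppressWarnings(as.integer(toks[bpPos - 1L]))
  topoTok <- intersect(tolower(toks), c("circular", "linear"))
  topologyKnown <- length(topoTok) == 1L
  topology <- if (topologyKnown) topoTok else "linear"

  kw <- function(key) grep(paste0("^", key), chunk)
  getBlock <- function(i0) {
    # keyword line plus its indented continuations
    if (!length(i0)) return(character())
    i0 <- i0[1]
    j <- i0 + 1L
    while (j <= length(chunk) && grepl("^\\s", chunk[j])) j <- j + 1L
    chunk[i0:(j - 1L)]
  }
  defBlock <- getBlock(kw("DEFINITION"))
  definition <- trimws(paste(sub("^DEFINITION", "", defBlock), collapse = " "))
  definition <- gsub("\\s+", " ", definition)
  accLine <- grep("^ACCESSION", chunk, value = TRUE)
  acc <- if (length(accLine)) {
    at <- strsplit(trimws(accLine[1]), "[[:space:]]+")[[1]]
    if (length(at) >= 2) at[2] else locusName
  } else locusName

  orgIdx <- grep("^\\s{1,4}ORGANISM", chunk)
  organism <- ""
  lin <- character()
  if (length(orgIdx)) {
    organism <- trimws(sub("^\\s*ORGANISM", "", chunk[orgIdx[1]]))
    j <- orgIdx[1] + 1L
    linLines <- character()
    while (j <= length(chunk) && grepl("^\\s{5,}\\S", chunk[j]) &&
           !grepl("^\\s{5}\\S+\\s{2,}", chunk[j])) {
      linLines <- c(linLines, trimws(chunk[j])); j <- j + 1L
    }
    lin <- trimws(strsplit(sub("\\.\\s*$", "", paste(linLines, collapse = " ")),
                           ";")[[1]])
    lin <- lin[nzchar(lin)]
  }

  featIdx <- grep("^FEATURES", chunk)
  origIdx <- grep("^ORIGIN", chunk)
  if (!length(origIdx)) stop("no ORIGIN sequence block")
  seqLines <- chunk[(origIdx[1] + 1L):length(chunk)]
  seqStr <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nchar(seqStr)) stop("empty sequence")
  sequence <- Biostrings::DNAString(seqStr)
  L <- length(sequence)
  if (!is.na(declaredLen) && declaredLen != L)
    stop(sprintf("LOCUS length %d disagrees with sequence length %d",
                 declaredLen, L))

  featureDiags <- data.frame(record = character(), unit = character(),
                             reason = character())
  featLines <- if (length(featIdx)) {
    end <- origIdx[1] - 1L
    if (end > featIdx[1]) chunk[(featIdx[1] + 1L):end] else character()
  } else character()
  parsed <- .parseFeatureTable(featLines, L, topology == "circular", acc)
  featureDiags <- parsed$diags
  ft <- parsed$features

  code <- ft$transl_table[ft$kind == "CDS"]
  code <- code[!is.na(code)]
  geneticCode <- if (length(code)) {
    as.integer(names(sort(table(code), decreasing = TRUE))[1])
  } else 1L

  rec <- methods::new("GenomeRecord",
    accession = acc, definition = definition, organism = organism,
    sequence = sequence, topology = topology, topologyKnown = topologyKnown,
    features = ft, lineage = lin, geneticCode = geneticCode)
  list(record = rec, featureDiags = featureDiags)
}

.parseFeatureTable <- function(featLines, L, circular, acc) {
  keys <- character(); locs <- character(); quals <- list()
  cur <- 0L; inLocation <- FALSE
  for (ln in featLines) {
    if (grepl("^ {5}\\S", ln) && !grepl("^ {6}", ln)) {
      m <- regmatches(ln, regexec("^ {5}(\\S+)\\s+(\\S.*)$", ln))[[1]]
      if (length(m) == 3) {
        cur <- cur + 1L
        keys[cur] <- m[2]; locs[cur] <- trimws(m[3])
        quals[[cur]] <- character(); inLocation <- TRUE
      }
    } else if (cur > 0L) {
      body <- trimws(ln)
      if (startsWith(body, "/")) {
        quals[[cur]] <- c(quals[[cur]], body); inLocation <- FALSE
      } else if (inLocation) {
        locs[cur] <- paste0(locs[cur], body)
      } else if (length(quals[[cur]])) {
        # continuation of a (quoted) qualifier value
        n <- length(quals[[cur]])
        quals[[cur]][n] <- paste(quals[[cur]][n], body)
      }
    }
  }
  rows <- list()
  diags <- list()
  for (i in seq_len(cur)) {
    key <- keys[i]
    if (key == "source") next
    kind <- if (key %in% c("gene", "CDS", "tRNA", "rRNA")) key else "other"
    loc <- .parseLocation(locs[i], L, circular)
    if (!is.null(loc$error)) {
      diags[[length(diags) + 1L]] <- data.frame(
        record = acc, unit = paste0(key, " ", locs[i]), reason = loc$error)
      next
    }
    q <- .parseQualifiers(quals[[i]])
    name <- q[["gene"]] %||% q[["product"]] %||% key
    tt <- suppressWarnings(as.integer(q[["transl_table"]] %||% NA))
    rows[[length(rows) + 1L]] <- list(
      kind = kind, name = name, strand = loc$strand,
      transl_table = tt, partial = loc$partial, intervals = loc$intervals)
  }
  diags <- if (length(diags)) do.call(rbind, diags) else
    data.frame(record = character(), unit = character(), reason = character())
  if (!length(rows)) {
    ft <- S4Vectors::DataFrame(
      kind = character(), name = character(), strand = character(),
      transl_table = integer(), partial = logical())
    ft$intervals <- list()
    return(list(features = ft, diags = diags))
  }
  ft <- S4Vectors::DataFrame(
    kind = vapply(rows, `[[`, "", "kind"),
    name = vapply(rows, `[[`, "", "name"),
    strand = vapply(rows, `[[`, "", "strand"),
    transl_table = vapply(rows, `[[`, NA_integer_, "transl_table"),
    partial = vapply(rows, `[[`, NA, "partial"))
  ft$intervals <- lapply(rows, `[[`, "intervals")
  list(features = ft, diags = diags)
}

.parseQualifiers <- function(qlines) {
  if (!length(qlines)) return(list())
  keys <- sub("^/([A-Za-z_0-9]+).*$", "\\1", qlines)
  hasVal <- grepl("^/[A-Za-z_0-9]+=", qlines)
  vals <- as.list(rep(TRUE, length(qlines)))
  vals[hasVal] <- gsub('^"|"$', "", sub("^/[A-Za-z_0-9]+=", "", qlines[hasVal]))
  stats::setNames(vals, keys)
}

# Resolve a GenBank location string into (intervals, strand, partial), or
# a list with an $error message for unsupported/out-of-bounds locations.
# Supported grammar: N, N..M, with optional < >, complement(...),
# join(...)/order(...), and complement(join(...)). Mixed-strand joins
# (per-segment complement inside a join) are rejected.
.parseLocation <- function(loc, L, circular) {
  loc1 <- gsub("[[:space:]]", "", loc)
  partial <- grepl("[<>]", loc1)
  if (partial) loc1 <- gsub("[<>]", "", loc1)
  strand <- "+"
  if (startsWith(loc1, "complement(") && endsWith(loc1, ")")) {
    strand <- "-"
    loc1 <- substr(loc1, 12L, nchar(loc1) - 1L)
  }
  if ((startsWith(loc1, "join(") || startsWith(loc1, "order(")) &&
      endsWith(loc1, ")")) {
    loc1 <- sub("^(join|order)\\(", "", substr(loc1, 1L, nchar(loc1) - 1L))
    if (grepl("(", loc1, fixed = TRUE))
      return(list(error = "nested or mixed-strand join locations are not supported"))
    parts <- strsplit(loc1, ",", fixed = TRUE)[[1]]
  } else {
    parts <- loc1
  }
  if (!all(grepl("^[0-9]+(\\.\\.[0-9]+)?$", parts)))
    return(list(error = sprintf("unsupported location '%s'", loc)))
  ab <- strsplit(parts, "..", fixed = TRUE)
  a <- as.integer(vapply(ab, `[`, "", 1L))
  b <- as.integer(vapply(ab, function(x) x[length(x)], ""))
  if (any(a < 1L | b < 1L | a > L | b > L))
    return(list(error = sprintf("location outside sequence 1..%d", L)))
  desc <- a > b
  if (any(desc) && !circular)
    return(list(error = "descending location on a linear record"))
  s <- a - 1L; e <- b; w <- desc
  # collapse a join that abuts across the origin of a circular record
  if (circular && length(s) >= 2L) {
    i <- 1L
    while (i < length(s)) {
      if (!w[i] && !w[i + 1L] && e[i] == L && s[i + 1L] == 0L) {
        e[i] <- e[i + 1L]; w[i] <- TRUE
        s <- s[-(i + 1L)]; e <- e[-(i + 1L)]; w <- w[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  list(intervals = .interval(s, e, w), strand = strand, partial = partial)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report computability issues of a parsed record
#'
#' A pure report of which of the eleven per-genome variables cannot be
#' computed for this record and why: at least one annotated gene is needed
#' for the unassigned-region metrics and at least one CDS for the codon
#' adaptation index, so records carrying only tRNAs (or no annotation at
#' all) are partially blind to the pipeline.
#'
#' @param record A \linkS4class{GenomeRecord}.
#' @return Character vector of issue codes among \code{NO_GENES},
#'   \code{NO_CDS}, \code{NO_LINEAGE}, \code{PARTIAL_FEATURES},
#'   \code{AMBIGUOUS_TOPOLOGY}; empty when all variables are computable.
#' @export
validateRecord <- function(record) {
  stopifnot(is(record, "GenomeRecord"))
  ft <- record@features
  issues <- character()
  if (nrow(geneSet(record)) == 0L) issues <- c(issues, "NO_GENES")
  if (!any(ft$kind == "CDS")) issues <- c(issues, "NO_CDS")
  if (length(record@lineage) == 0L) issues <- c(issues, "NO_LINEAGE")
  if (nrow(ft) > 0L && any(ft$partial)) issues <- c(issues, "PARTIAL_FEATURES")
  if (!record@topologyKnown) issues <- c(issues, "AMBIGUOUS_TOPOLOGY")
  issues
}

#' The gene set of a record
#'
#' GenBank records annotate genes inconsistently: some carry explicit
#' \code{gene} features, others only product features. The gene set used
#' for the gene count, the strand-usage skew, unassigned-region coverage
#' and the strand audit is the \code{gene} features when any exist, and
#' otherwise the union of CDS/tRNA/rRNA features deduplicated by identical
#' span (strand + intervals).
#'
#' @param record A \linkS4class{GenomeRecord}.
#' @return \link[S4Vectors]{DataFrame} of features, same columns as
#'   \code{features(record)}.
#' @export
geneSet <- function(record) {
  ft <- record@features
  g <- ft[ft$kind == "gene", , drop = FALSE]
  if (nrow(g) > 0L) return(g)
  p <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (nrow(p) == 0L) return(p)
  keys <- mapply(.spanKey, p$intervals, p$strand)
  p[!duplicated(keys), , drop = FALSE]
}

#' Extract in-frame coding sequences
#'
#' Returns the 5'->3' coding nucleotide sequence of every CDS feature after
#' join concatenation, reverse complementation of minus-strand features and
#' unwrapping of origin-spanning intervals. Lengths need not be multiples
#' of 3; trailing partial codons are dropped downstream by \code{\link{cai}}.
#'
#' @param record A \linkS4class{GenomeRecord}.
#' @return Named \link[Biostrings]{DNAStringSet} (one element per CDS; may
#'   be empty).
#' @export
extractCDS <- function(record) {
  stopifnot(is(record, "GenomeRecord"))
  Biostrings::DNAStringSet(.extractCDSChr(record))
}

# character-vector workhorse behind extractCDS (also the CAI hot path)
.extractCDSChr <- function(record, seqChr = as.character(record@sequence)) {
  ft <- record@features
  idx <- which(ft$kind == "CDS")
  L <- nchar(seqChr)
  out <- character()
  for (i in idx) {
    iv <- ft$intervals[[i]]
    if (any(ifelse(iv$wraps, iv$start >= L | iv$end > L,
                   iv$start < 0L | iv$end > L))) {
      warning(sprintf("CDS '%s' of %s skipped: intervals exceed sequence bounds",
                      ft$name[i], record@accession), call. = FALSE)
      next
    }
    out <- c(out, stats::setNames(.featureSeqChr(seqChr, iv, ft$strand[i], L),
                                  ft$name[i]))
  }
  out
}
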