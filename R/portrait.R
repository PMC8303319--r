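#' The versioned portrait column schema
#'
#' Column order of a \linkS4class{PortraitTable}: identifiers (accession,
#' definition, organism), the eleven per-genome variables, computability
#' flags, taxonomy placements (subdivision, major group, matched labels,
#' plant grade, best-effort superkingdom/kingdom/phylum ranks), the
#' genetic code, and four ecology placeholder columns (func_adult,
#' func_larva, feed_adult, feed_larva) kept for schema compatibility with
#' externally populated ecological annotations (functional group and
#' feeding type per life stage); they are emitted as NA here since their
#' population requires a network service. Missing values are encoded as
#' the single token \code{NA}.
#'
#' @return Character vector of column names (schema version in
#'   \code{attr(, "version")}).
#' @export
portraitColumns <- function() {
  structure(c("accession", "definition", "organism",
              "length_bp", "topology", "n_genes", "su_skew", "at_content",
              "at_skew", "gc_skew", "cai", "ur_percent", "ur_at_content",
              "ur_median_length", "flags",
              "superkingdom", "kingdom", "phylum",
              "subdivision", "major_group", "group_labels", "plant_grade",
              "genetic_code",
              "func_adult", "func_larva", "feed_adult", "feed_larva"),
            version = "1")
}

.majorGroups <- c("Metazoa", "Fungi", "Viridiplantae", "Alveolata",
                  "Stramenopiles", "Rhizaria", "Amoebozoa", "Excavata",
                  "Discoba", "Haptista")

#' Assemble the portrait table from parsed records
#'
#' Computes the eleven variables and the taxonomy placement for each
#' record and binds them into a \linkS4class{PortraitTable} following the
#' \code{\link{portraitColumns}} schema. Records are never dropped here:
#' partial computability shows up as NA cells plus flags (use
#' \code{\link{runPipeline}} for the discard accounting of unparseable
#' input).
#'
#' @param records List of \linkS4class{GenomeRecord}.
#' @param rules Subdivision rule table
#'   (\code{\link{defaultSubdivisionRules}}).
#' @return A \linkS4class{PortraitTable}.
#' @export
buildPortraitTable <- function(records, rules = defaultSubdivisionRules()) {
  if (is(records, "GenomeRecord")) records <- list(records)
  rows <- lapply(records, function(rec) {
    m <- computeMetrics(rec)
    pl <- assignSubdivision(rec@lineage, rules)
    major <- intersect(pl$group_labels, .majorGroups)
    rk <- pl$rank_map
    data.frame(
      accession = rec@accession, definition = rec@definition,
      organism = rec@organism,
      m[, c("length_bp", "topology", "n_genes", "su_skew", "at_content",
            "at_skew", "gc_skew", "cai", "ur_percent", "ur_at_content",
            "ur_median_length", "flags")],
      superkingdom = rk["superkingdom"] %NA% NA_character_,
      kingdom = rk["kingdom"] %NA% NA_character_,
      phylum = rk["phylum"] %NA% NA_character_,
      subdivision = pl$subdivision,
      major_group = if (length(major)) major[1] else NA_character_,
      group_labels = paste(pl$group_labels, collapse = ";"),
      plant_grade = plantGrade(rec@lineage),
      genetic_code = rec@geneticCode,
      func_adult = NA_character_, func_larva = NA_character_,
      feed_adult = NA_character_, feed_larva = NA_character_,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(portraitColumns())), portraitColumns()))
  }
  PortraitTable(df)
}

`%NA%` <- function(a, b) if (length(a) == 1L && !is.na(a)) unname(a) else b

#' Run the end-to-end pipeline over GenBank files
#'
#' Parses every readable GenBank file, computes the portrait of every
#' parseable record and writes the table as CSV. The log accounts for
#' every input record: accepted + discarded = seen; discarded records
#' (malformed, no sequence) keep their diagnostic reason, mirroring how
#' corpus mining discards unsuitable entries.
#'
#' @param paths Character vector of GenBank file paths (or a directory,
#'   expanded to \code{*.gb}/\code{*.gbk}/\code{*.gbff}).
#' @param output Optional CSV path for the portrait table; a log is
#'   written next to it as \code{<output>.log.csv}.
#' @param rules Subdivision rule table.
#' @param maxPerSpecies Optional cap on records per species (see
#'   \code{\link{dedupOverrepresented}}); NULL disables (the default).
#' @return Invisibly, a list with \code{table} (the
#'   \linkS4class{PortraitTable}) and \code{log} (data.frame with columns
#'   \code{record}, \code{unit}, \code{status}, \code{reason}).
#' @export
runPipeline <- function(paths, output = NULL,
                        rules = defaultSubdivisionRules(),
                        maxPerSpecies = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(gb|gbk|gbff)$",
                        full.names = TRUE)
  if (!length(paths)) {
    warning("runPipeline: no input files")
    return(invisible(list(table = buildPortraitTable(list()),
                          log = data.frame(record = character(),
                                           unit = character(),
                                           status = character(),
                                           reason = character()))))
  }
  bad <- paths[!file.exists(paths)]
  if (length(bad)) stop("unreadable input path(s): ", paste(bad, collapse = ", "))
  records <- list()
  logRows <- list()
  for (p in paths) {
    recs <- parseGenBank(p)
    dg <- attr(recs, "diagnostics")
    if (nrow(dg))
      logRows[[length(logRows) + 1L]] <- data.frame(
        record = dg$record, unit = dg$unit, status = "discarded",
        reason = dg$reason, stringsAsFactors = FALSE)
    if (length(recs))
      logRows[[length(logRows) + 1L]] <- data.frame(
        record = names(recs), unit = "record", status = "accepted",
        reason = "", stringsAsFactors = FALSE)
    records <- c(records, recs)
  }
  log <- do.call(rbind, logRows)
  pt <- buildPortraitTable(records, rules)
  if (!is.null(maxPerSpecies)) pt <- dedupOverrepresented(pt, maxPerSpecies)
  if (!is.null(output)) {
    writePortraitCSV(pt, output)
    utils::write.csv(log, paste0(output, ".log.csv"), row.names = FALSE)
  }
  invisible(list(table = pt, log = log))
}

#' Cap records per species
#'
#' Automated surrogate for the manual curation of overrepresented
#' species: keeps at most \code{maxPerSpecies} rows per organism name, in
#' first-seen order. A cap of 0 removes a species entirely.
#'
#' @param x A \linkS4class{PortraitTable}.
#' @param maxPerSpecies Non-negative integer.
#' @return The filtered \linkS4class{PortraitTable}.
#' @export
dedupOverrepresented <- function(x, maxPerSpecies) {
  stopifnot(is(x, "PortraitTable"), maxPerSpecies >= 0)
  sp <- x$organism
  keep <- stats::ave(seq_along(sp), sp, FUN = seq_along) <= maxPerSpecies
  x[keep, , drop = FALSE]
}

#' Write / read the portrait table as CSV
#'
#' Numeric fields are written at full double precision (15 significant
#' digits) so that a read round-trip reproduces all values as written;
#' missing cells use the single token \code{NA}.
#'
#' @param x A \linkS4class{PortraitTable}.
#' @param path CSV path.
#' @return \code{writePortraitCSV}: invisibly, \code{path};
#'   \code{readPortraitCSV}: a \linkS4class{PortraitTable}.
#' @export
writePortraitCSV <- function(x, path) {
  stopifnot(is(x, "PortraitTable"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writePortraitCSV
#' @export
readPortraitCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(accession = "character"))
  # structural string columns: an absent value means "none", not missing
  for (cc in c("flags", "group_labels")) {
    if (!cc %in% names(df)) next
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][is.na(df[[cc]])] <- ""
  }
  for (cc in c("func_adult", "func_larva", "feed_adult", "feed_larva"))
    if (cc %in% names(df)) df[[cc]] <- as.character(df[[cc]])
  PortraitTable(df)
}

#' Construct a PortraitTable from a schema-conforming data.frame
#'
#' @param df data.frame (or \link[S4Vectors]{DataFrame}) carrying at least
#'   the \code{\link{portraitColumns}}.
#' @return A \linkS4class{PortraitTable}.
#' @export
PortraitTable <- function(df) {
  pt <- methods::new("PortraitTable",
                     S4Vectors::DataFrame(df, check.names = FALSE))
  S4Vectors::metadata(pt)$schema_version <- attr(portraitColumns(), "version")
  pt
}
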