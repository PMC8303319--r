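#' Default subdivision rule table
#'
#' Keyword rules placing lineage names into the major eukaryotic
#' subdivisions: Diaphoretickes (Archaeplastida including Viridiplantae,
#' Excavata, Haptista, and the SAR clade: Stramenopiles, Alveolata,
#' Rhizaria), Amorphea (Amoebozoa and Opisthokonta, including Fungi and
#' Metazoa), and CRuMs (Collodictyonidae, Rigifilida, Mantamonas).
#' Excavata lineages are also matched via "Discoba", the name NCBI lineage
#' strings use. Virus, bacterial and archaeal lineages map to
#' \code{non_eukaryote} and are excluded from downstream aggregations.
#'
#' The table ships as plain text in
#' \code{system.file("extdata", "subdivision_rules.tsv", package =
#' "MitoPortrait")} and can be replaced or extended; matching never fails
#' (unmatched lineages fall back to \code{incertae_sedis}).
#'
#' @param path Optional path to an alternative rule table (TSV with
#'   columns \code{taxon}, \code{subdivision}, \code{rank}).
#' @return data.frame with columns \code{taxon}, \code{subdivision},
#'   \code{rank} (NA where no rank is asserted).
#' @export
defaultSubdivisionRules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "subdivision_rules.tsv",
                        package = "MitoPortrait")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Place a lineage into the major eukaryotic subdivisions
#'
#' Case-insensitive keyword matching of the record's own lineage string
#' against a rule table; the most specific (deepest) matched clade
#' determines the subdivision. Empty or unmatched eukaryote lineages map
#' to \code{incertae_sedis}; virus/prokaryote lineages to
#' \code{non_eukaryote}.
#'
#' @param lineage Character vector of taxon names, root first.
#' @param rules Rule table (see \code{\link{defaultSubdivisionRules}}).
#' @return List with elements \code{subdivision} (one of Amorphea,
#'   Diaphoretickes, CRuMs, incertae_sedis, non_eukaryote),
#'   \code{group_labels} (matched clade names in lineage order) and
#'   \code{rank_map} (named character, sparse best-effort rank
#'   assignments).
#' @examples
#' assignSubdivision(c("Eukaryota", "Opisthokonta", "Metazoa", "Chordata"))
#' @export
assignSubdivision <- function(lineage, rules = defaultSubdivisionRules()) {
  lineage <- lineage[nzchar(lineage)]
  if (length(lineage) == 0L)
    return(list(subdivision = "incertae_sedis", group_labels = character(),
                rank_map = character()))
  hit <- match(tolower(lineage), tolower(rules$taxon))
  matched <- which(!is.na(hit))
  labels <- lineage[matched]
  subs <- rules$subdivision[hit[matched]]
  subdivision <- if ("non_eukaryote" %in% subs) {
    "non_eukaryote"
  } else if (length(subs)) {
    subs[length(subs)]  # deepest match wins
  } else "incertae_sedis"
  rank_map <- character()
  rk <- rules$rank[hit[matched]]
  keep <- !is.na(rk)
  if (any(keep)) rank_map <- stats::setNames(labels[keep], rk[keep])
  if (tolower(lineage[1]) == "eukaryota" && !"superkingdom" %in% names(rank_map))
    rank_map <- c(rank_map, superkingdom = lineage[1])
  list(subdivision = subdivision, group_labels = labels, rank_map = rank_map)
}

#' Grade a Viridiplantae lineage along the water-to-land transition
#'
#' Classifies a plant lineage into the grades used for mitogenome
#' expansion summaries: Chlorophyta, non-embryophyte Streptophyta
#' (freshwater green algae), non-vascular Embryophyta (mosses, liverworts,
#' hornworts), and Tracheophyta (vascular plants). Non-plant lineages
#' return \code{"other"}.
#'
#' @param lineage Character vector of taxon names.
#' @return One of \code{"Chlorophyta"},
#'   \code{"non-embryophyte Streptophyta"},
#'   \code{"non-vascular Embryophyta"}, \code{"Tracheophyta"},
#'   \code{"other"}.
#' @export
plantGrade <- function(lineage) {
  low <- tolower(lineage)
  if (!"viridiplantae" %in% low) return("other")
  if ("tracheophyta" %in% low) return("Tracheophyta")
  if ("embryophyta" %in% low) return("non-vascular Embryophyta")
  if ("streptophyta" %in% low) return("non-embryophyte Streptophyta")
  if ("chlorophyta" %in% low) return("Chlorophyta")
  "other"
}

#' Normalize a mitochondrial gene name
#'
#' GenBank gene naming is inconsistent (cox1 = COI = COX1 = CO1, cytb =
#' cob, nad = ND, atp = ATPase ...). Normalization lower-cases, strips
#' punctuation and maps synonyms onto the canonical lowercase names
#' (cox1-3, cytb, nad1-6/nad4l, atp6/atp8, rrnS/rrnL, trnX). Needed to
#' identify cox1 in the strand-convention audit.
#'
#' @param x Character vector of gene or product labels.
#' @return Character vector of normalized names.
#' @examples
#' normalizeGeneName(c("COI", "COX1", "cytochrome b", "ND4L", "ATPase 6"))
#' @export
normalizeGeneName <- function(x) {
  vapply(x, function(nm) {
    s <- tolower(nm)
    # common long-form products
    if (grepl("cytochrome c oxidase subunit", s) || grepl("cytochrome oxidase", s)) {
      if (grepl("iii|3", s)) return("cox3")
      if (grepl("ii|2", s)) return("cox2")
      return("cox1")
    }
    if (grepl("cytochrome b|apocytochrome", s)) return("cytb")
    if (grepl("nadh.*dehydrogenase.*subunit", s)) {
      m <- regmatches(s, regexec("subunit\\s*([1-6])\\s*(l)?", s))[[1]]
      if (length(m) >= 2) return(paste0("nad", m[2], if (length(m) >= 3) m[3]))
    }
    if (grepl("atp.*synthase.*subunit", s)) {
      m <- regmatches(s, regexec("subunit\\s*([689])", s))[[1]]
      if (length(m) >= 2) return(paste0("atp", m[2]))
    }
    if (grepl("12s|small subunit ribosomal", s)) return("rrnS")
    if (grepl("16s|large subunit ribosomal", s)) return("rrnL")
    t <- gsub("[^a-z0-9]", "", s)
    if (grepl("^(mt)?(co|cox)(1|i)$", t)) return("cox1")
    if (grepl("^(mt)?(co|cox)(2|ii)$", t)) return("cox2")
    if (grepl("^(mt)?(co|cox)(3|iii)$", t)) return("cox3")
    if (grepl("^(mt)?(cytb|cob|cyb)$", t)) return("cytb")
    m <- regmatches(t, regexec("^(mt)?(nad|ndh|nd)([1-6])(l)?$", t))[[1]]
    if (length(m) == 5) return(paste0("nad", m[4], m[5]))
    m <- regmatches(t, regexec("^(mt)?(atp|atpase)([689])$", t))[[1]]
    if (length(m) == 4) return(paste0("atp", m[4]))
    if (grepl("^(rrns|srrna|rns|12srrna)$", t)) return("rrnS")
    if (grepl("^(rrnl|lrrna|rnl|16srrna)$", t)) return("rrnL")
    if (grepl("^trn", t)) return(t)
    t
  }, character(1), USE.NAMES = FALSE)
}
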