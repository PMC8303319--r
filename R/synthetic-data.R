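#' Specification of a synthetic mitochondrial record
#'
#' Bundles the parameters from which \code{\link{generateGenome}} builds a
#' GenBank-format record with analytically known ground truth. Defaults
#' emulate a typical circular metazoan mitogenome: 37 genes (13
#' protein-coding, 2 rRNA, 22 tRNA) with the common bilaterian names, most
#' genes on the plus strand, the vertebrate mitochondrial code (transl_table
#' 2), ~7% unassigned (intergenic) sequence, and a plus strand enriched in
#' A over T and C over G (positive AT-skew, negative GC-skew — the common
#' "normal" metazoan asymmetry).
#'
#' Codon usage of synthesized CDSs is controlled by either
#' \code{codonWeights} (explicit per-codon weights), \code{codonBias}
#' (geometric within-family bias: weight \code{b^(rank-1)} with codons
#' ranked by base-composition preference; \code{b = 0} forces a single
#' codon per family, \code{b = 1} is uniform) or, when both are NULL, by
#' the product of \code{baseWeights} over the codon's three bases, which
#' ties coding-region composition to the intergenic composition.
#'
#' @param length Total sequence length (bp). When NULL, derived from the
#'   gene layout and \code{urFraction}.
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param baseWeights Named probabilities over A, C, G, T for intergenic /
#'   RNA-gene bases (and, indirectly, codon choice).
#' @param geneLayout data.frame with columns \code{kind} (CDS/tRNA/rRNA),
#'   \code{name}, \code{length} (bp; CDS lengths must be multiples of 3),
#'   \code{strand} (\code{"+"}/\code{"-"}).
#' @param urFraction Target fraction of unassigned sequence (used only
#'   when \code{length} is NULL).
#' @param codonWeights Optional named weights over codons.
#' @param codonBias Optional within-family geometric bias in [0, 1].
#' @param geneticCode NCBI translation-table id used for CDS synthesis and
#'   written into \code{/transl_table}.
#' @param lineage,organism,accession Taxonomic and identifier strings
#'   embedded in the record.
#' @param wrap Origin handling on circular records: \code{"gene"} places
#'   the first gene across the origin (an origin-spanning join),
#'   \code{"gap"} places an unassigned region across the origin,
#'   \code{"none"} starts the layout at position 1.
#' @param splitFirstCDS Emit the first (non-wrapped) CDS location as a
#'   join of two abutting spans, to exercise join parsing.
#' @param seed Integer; fixes all randomness of the realization.
#' @return A list of class \code{"genomeSpec"}.
#' @export
genomeSpec <- function(length = NULL, topology = "circular",
                       baseWeights = c(A = 0.30, C = 0.26, G = 0.17, T = 0.27),
                       geneLayout = defaultGeneLayout(),
                       urFraction = 0.07,
                       codonWeights = NULL, codonBias = NULL,
                       geneticCode = 2L,
                       lineage = c("Eukaryota", "Opisthokonta", "Metazoa",
                                   "Chordata", "Craniata", "Vertebrata"),
                       organism = "Synthomys exemplaris",
                       accession = "MPSYN001",
                       wrap = if (topology == "circular") "gene" else "none",
                       splitFirstCDS = FALSE,
                       seed = 1L) {
  stopifnot(topology %in% c("circular", "linear"),
            wrap %in% c("gene", "gap", "none"),
            all(c("A", "C", "G", "T") %in% names(baseWeights)),
            all(c("kind", "name", "length", "strand") %in% colnames(geneLayout)))
  baseWeights <- baseWeights[c("A", "C", "G", "T")] / sum(baseWeights)
  geneBp <- sum(geneLayout$length)
  if (is.null(length)) {
    stopifnot(urFraction >= 0, urFraction < 1)
    length <- as.integer(round(geneBp / (1 - urFraction)))
  }
  if (any(geneLayout$kind == "CDS" & geneLayout$length %% 3 != 0))
    stop("CDS lengths must be multiples of 3")
  if (geneBp > length)
    stop("infeasible layout: genes (", geneBp, " bp) overflow length ", length)
  if (topology == "linear" && wrap != "none")
    stop("wrap requires a circular topology")
  structure(list(
    length = as.integer(length), topology = topology,
    baseWeights = baseWeights, geneLayout = geneLayout,
    codonWeights = codonWeights, codonBias = codonBias,
    geneticCode = as.integer(geneticCode), lineage = lineage,
    organism = organism, accession = accession, wrap = wrap,
    splitFirstCDS = isTRUE(splitFirstCDS), seed = as.integer(seed)),
    class = "genomeSpec")
}

#' Standard and compact synthetic gene layouts
#'
#' \code{defaultGeneLayout} is the typical bilaterian complement: 13
#' protein-coding genes (nad1-6, nad4l, cox1-3, cytb, atp6, atp8), two
#' rRNAs and 22 tRNAs at realistic lengths, with a vertebrate-like strand
#' distribution (nad6 and eight tRNAs on the minus strand).
#' \code{compactGeneLayout} is a miniature layout (3 CDS, 1 rRNA, 2 tRNA,
#' ~0.8 kb) for fast randomized testing.
#'
#' @param minusGenes Names to place on the minus strand.
#' @return data.frame with columns \code{kind}, \code{name}, \code{length},
#'   \code{strand}.
#' @export
defaultGeneLayout <- function(minusGenes = c("nad6", "trnQ", "trnA", "trnN",
                                             "trnC", "trnY", "trnS2", "trnE",
                                             "trnP")) {
  cds <- data.frame(
    kind = "CDS",
    name = c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
             "nad4l", "nad4", "nad5", "nad6", "cytb", "nad1"),
    length = c(1038L, 1545L, 684L, 168L, 678L, 783L, 348L,
               294L, 1377L, 1812L, 522L, 1140L, 954L))
  rrn <- data.frame(kind = "rRNA", name = c("rrnS", "rrnL"),
                    length = c(951L, 1572L))
  trnNames <- c("trnF", "trnV", "trnL2", "trnI", "trnQ", "trnM", "trnW",
                "trnA", "trnN", "trnC", "trnY", "trnS2", "trnD", "trnK",
                "trnG", "trnR", "trnH", "trnS1", "trnL1", "trnE", "trnT",
                "trnP")
  trn <- data.frame(kind = "tRNA", name = trnNames,
                    length = rep(c(69L, 71L), length.out = length(trnNames)))
  # interleave tRNAs between the larger genes, roughly as in vertebrates
  big <- rbind(rrn[1, ], trn[1:2, ], rrn[2, ], trn[3, ], cds[13, ],
               trn[4:6, ], cds[1, ], trn[7:11, ], cds[2:3, ], trn[12:14, ],
               cds[4:7, ], trn[15, ], cds[8:10, ], trn[16:18, ], cds[11, ],
               trn[19, ], cds[12, ], trn[20:22, ])
  big$strand <- ifelse(big$name %in% minusGenes, "-", "+")
  rownames(big) <- NULL
  big
}

#' @rdname defaultGeneLayout
#' @export
compactGeneLayout <- function(minusGenes = c("nad6", "trnQ")) {
  df <- data.frame(
    kind = c("CDS", "tRNA", "CDS", "rRNA", "CDS", "tRNA"),
    name = c("cox1", "trnQ", "cytb", "rrnS", "nad6", "trnM"),
    length = c(201L, 63L, 150L, 120L, 99L, 63L))
  df$strand <- ifelse(df$name %in% minusGenes, "-", "+")
  df
}

# Global codon sampling weights for CDS synthesis (stop codons excluded).
.codonSamplingWeights <- function(spec, gcode) {
  codons <- names(gcode)[gcode != "*"]
  baseP <- spec$baseWeights
  prodW <- vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    prod(baseP[b])
  }, numeric(1))
  if (!is.null(spec$codonWeights)) {
    w <- spec$codonWeights[codons]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) stop("codonWeights assign no mass to non-stop codons")
    return(w / sum(w))
  }
  if (!is.null(spec$codonBias)) {
    b <- spec$codonBias
    stopifnot(b >= 0, b <= 1)
    fams <- split(codons, gcode[codons])
    w <- stats::setNames(numeric(length(codons)), codons)
    for (f in fams) {
      pref <- order(prodW[f], decreasing = TRUE)
      # keep the forced ATG start codon at rank 1 of its own family so that
      # codonBias = 0 realizes exactly one codon per family
      if ("ATG" %in% f) pref <- c(match("ATG", f), setdiff(pref, match("ATG", f)))
      within <- if (b == 0) c(1, rep(0, length(f) - 1L)) else b^(seq_along(f) - 1L)
      w[f[pref]] <- within / sum(within) / length(fams)
    }
    return(w / sum(w))
  }
  prodW / sum(prodW)
}

#' Generate a synthetic GenBank record with exact ground truth
#'
#' Realizes a \code{\link{genomeSpec}} into GenBank flat-file text plus a
#' ground-truth row computed by construction-time bookkeeping (realized
#' counts, not distribution parameters), independently of the parsing and
#' metric code under test. CDS regions are synthesized codon-wise (ATG
#' start, no internal stop under the declared code, TAA stop); intergenic
#' and RNA-gene bases are drawn i.i.d. from \code{baseWeights};
#' minus-strand genes are inserted as reverse complements and written as
#' \code{complement(...)} locations; an origin-spanning gene or gap is
#' emitted when requested.
#'
#' @param spec A \code{\link{genomeSpec}}.
#' @return List with elements \code{text} (character scalar, the GenBank
#'   record), \code{truth} (one-row data.frame with the eleven variables
#'   plus \code{n_plus}, \code{n_minus}, \code{cox1_strand}),
#'   \code{urIntervals} (data.frame, 0-based half-open realized unassigned
#'   regions) and \code{spec}.
#' @examples
#' g <- generateGenome(genomeSpec(seed = 42))
#' g$truth$ur_percent
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "genomeSpec"))
  set.seed(spec$seed)
  L <- spec$length
  layout <- spec$geneLayout
  nG <- nrow(layout)
  circular <- spec$topology == "circular"
  gcode <- Biostrings::getGeneticCode(as.character(spec$geneticCode))
  codonW <- .codonSamplingWeights(spec, gcode)
  bases <- c("A", "C", "G", "T")

  urBp <- L - sum(layout$length)
  nGaps <- if (circular) nG else nG + 1L
  gapLens <- if (urBp > 0) {
    as.vector(stats::rmultinom(1, urBp, rep(1, nGaps)))
  } else rep(0L, nGaps)

  # block order: (linear) gap0 gene1 gap1 ... geneN gapN
  #              (circular) gene1 gap1 ... geneN gapN
  blocks <- list()
  if (!circular)
    blocks[[1]] <- list(type = "gap", idx = 0L, len = gapLens[nGaps])
  for (i in seq_len(nG)) {
    blocks[[length(blocks) + 1L]] <- list(type = "gene", idx = i,
                                          len = layout$length[i])
    blocks[[length(blocks) + 1L]] <- list(type = "gap", idx = i,
                                          len = gapLens[i])
  }

  codonTally <- integer(0)
  gapAT <- 0L; gapACGT <- 0L
  segs <- character(length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (b$len == 0L) { segs[bi] <- ""; next }
    if (b$type == "gene" && layout$kind[b$idx] == "CDS") {
      nCod <- b$len %/% 3L
      body <- if (nCod > 2L)
        sample(names(codonW), nCod - 2L, replace = TRUE, prob = codonW)
      else character()
      cods <- c("ATG", body, "TAA")[seq_len(max(nCod, 0L))]
      if (nCod >= 2L) cods[nCod] <- "TAA"
      tt <- table(cods)
      for (cd in names(tt))
        codonTally[cd] <- (if (is.na(codonTally[cd])) 0L else codonTally[cd]) + tt[[cd]]
      coding <- paste(cods, collapse = "")
      segs[bi] <- if (layout$strand[b$idx] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
      } else coding
    } else {
      s <- paste(sample(bases, b$len, replace = TRUE, prob = spec$baseWeights),
                 collapse = "")
      segs[bi] <- s
      if (b$type == "gap") {
        cnt <- .charCounts(s)
        gapAT <- gapAT + cnt["A"] + cnt["T"]
        gapACGT <- gapACGT + sum(cnt)
      }
    }
  }
  linearSeq <- paste(segs, collapse = "")
  stopifnot(nchar(linearSeq) == L)

  # rotation so that a gene or a gap spans the origin
  offset <- 0L
  if (circular && spec$wrap == "gene") {
    offset <- L - layout$length[1] %/% 2L
  } else if (circular && spec$wrap == "gap") {
    gN <- gapLens[nGaps]
    if (gN >= 2L) offset <- gN %/% 2L
  }
  plusSeq <- if (offset %% L == 0L) linearSeq else {
    off <- offset %% L
    paste0(substring(linearSeq, L - off + 1L, L), substring(linearSeq, 1L, L - off))
  }

  # rotated feature and gap intervals (0-based half-open)
  blockStart <- cumsum(c(0L, vapply(blocks, `[[`, 0L, "len")))
  rotate <- function(bs, len) {
    s0 <- (bs + offset) %% L
    e0 <- s0 + len
    if (e0 > L) .interval(s0, e0 - L, TRUE) else .interval(s0, e0, FALSE)
  }
  geneIv <- vector("list", nG)
  gapIv <- .emptyIntervals()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (b$len == 0L) next
    iv <- rotate(blockStart[bi], b$len)
    if (b$type == "gene") geneIv[[b$idx]] <- iv else gapIv <- rbind(gapIv, iv)
  }
  if (nrow(gapIv)) {
    gapIv$width <- .intervalWidth(gapIv, L)
    gapIv <- gapIv[order(gapIv$start), , drop = FALSE]
    rownames(gapIv) <- NULL
  } else gapIv$width <- integer(0)

  text <- .writeGenBankText(spec, plusSeq, layout, geneIv, gcode)

  # --- ground-truth bookkeeping (independent of the pipeline code path) ---
  cnt <- .charCounts(plusSeq)
  nA <- cnt["A"]; nC <- cnt["C"]; nG_ <- cnt["G"]; nT <- cnt["T"]
  truthCai <- .truthCAI(codonTally, gcode)
  np <- sum(layout$strand == "+"); nm <- sum(layout$strand == "-")
  coxStrand <- {
    s <- layout$strand[layout$name == "cox1"]
    if (length(s) == 1L) s else NA_character_
  }
  truth <- data.frame(
    accession = spec$accession,
    length_bp = L,
    topology = spec$topology,
    n_genes = nG,
    su_skew = if (nG > 0) abs(np - nm) / (np + nm) else NA_real_,
    at_content = unname(100 * (nA + nT) / (nA + nC + nG_ + nT)),
    at_skew = unname(if (nA + nT > 0) (nA - nT) / (nA + nT) else NA_real_),
    gc_skew = unname(if (nG_ + nC > 0) (nG_ - nC) / (nG_ + nC) else NA_real_),
    cai = truthCai,
    ur_percent = 100 * urBp / L,
    ur_at_content = if (gapACGT > 0) unname(100 * gapAT / gapACGT) else NA_real_,
    ur_median_length = if (nrow(gapIv)) stats::median(gapIv$width) else NA_real_,
    n_plus = np, n_minus = nm, cox1_strand = coxStrand,
    stringsAsFactors = FALSE)
  list(text = text, truth = truth, urIntervals = gapIv, spec = spec)
}

.charCounts <- function(s) {
  tab <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  stats::setNames(as.integer(tab), names(tab))
}

# Independent CAI bookkeeping: direct product over within-family
# adaptiveness values of the codons actually emitted.
.truthCAI <- function(tally, gcode) {
  if (!length(tally)) return(NA_real_)
  aa <- gcode[names(tally)]
  keep <- aa != "*"
  famSize <- table(gcode[gcode != "*"])
  keep <- keep & famSize[aa] > 1
  tally <- tally[keep]
  if (!length(tally)) return(NA_real_)
  aa <- gcode[names(tally)]
  total <- sum(tally)
  acc <- 0
  for (f in unique(aa)) {
    n <- tally[aa == f]
    w <- n / max(n)
    acc <- acc + sum(n * log(w))
  }
  exp(acc / total)
}

.locationString <- function(iv, strand, L, splitAt = NULL) {
  parts <- character()
  for (i in seq_len(nrow(iv))) {
    if (iv$wraps[i]) {
      parts <- c(parts, sprintf("%d..%d", iv$start[i] + 1L, L),
                 sprintf("%d..%d", 1L, iv$end[i]))
    } else if (!is.null(splitAt)) {
      parts <- c(parts, sprintf("%d..%d", iv$start[i] + 1L, splitAt),
                 sprintf("%d..%d", splitAt + 1L, iv$end[i]))
    } else {
      parts <- c(parts, sprintf("%d..%d", iv$start[i] + 1L, iv$end[i]))
    }
  }
  s <- if (length(parts) > 1L) paste0("join(", paste(parts, collapse = ","), ")")
       else parts
  if (strand == "-") paste0("complement(", s, ")") else s
}

.writeGenBankText <- function(spec, plusSeq, layout, geneIv, gcode) {
  L <- spec$length
  out <- character()
  out <- c(out, sprintf("LOCUS       %-17s%11d bp    DNA     %-8s INV 01-JAN-2026",
                        spec$accession, L, spec$topology))
  out <- c(out, sprintf("DEFINITION  %s mitochondrion, complete genome.",
                        spec$organism))
  out <- c(out, sprintf("ACCESSION   %s", spec$accession))
  out <- c(out, sprintf("VERSION     %s.1", spec$accession))
  out <- c(out, sprintf("SOURCE      mitochondrion %s", spec$organism))
  out <- c(out, sprintf("  ORGANISM  %s", spec$organism))
  lin <- paste0(paste(spec$lineage, collapse = "; "), ".")
  out <- c(out, paste0("            ", strwrap(lin, width = 66)))
  out <- c(out, "FEATURES             Location/Qualifiers")
  fmt <- function(key, loc) sprintf("     %-16s%s", key, loc)
  qual <- function(q) paste0("                     ", q)
  out <- c(out, fmt("source", sprintf("1..%d", L)),
           qual(sprintf('/organism="%s"', spec$organism)),
           qual('/organelle="mitochondrion"'),
           qual('/mol_type="genomic DNA"'))
  productOf <- function(name, kind) {
    if (kind == "tRNA") return(paste0("tRNA-", sub("^trn", "", name)))
    if (kind == "rRNA") return(if (name == "rrnS") "12S ribosomal RNA"
                               else "16S ribosomal RNA")
    switch(name,
           cox1 = "cytochrome c oxidase subunit I",
           cox2 = "cytochrome c oxidase subunit II",
           cox3 = "cytochrome c oxidase subunit III",
           cytb = "cytochrome b",
           paste("hypothetical protein", name))
  }
  firstCDSDone <- FALSE
  for (i in seq_len(nrow(layout))) {
    iv <- geneIv[[i]]
    strand <- layout$strand[i]
    kind <- layout$kind[i]
    splitAt <- NULL
    if (spec$splitFirstCDS && kind == "CDS" && !firstCDSDone && !any(iv$wraps)) {
      mid <- iv$start[1] + (iv$end[1] - iv$start[1]) %/% 2L
      if (mid > iv$start[1] && mid < iv$end[1]) splitAt <- mid
    }
    loc <- .locationString(iv, strand, L, splitAt)
    out <- c(out, fmt("gene", loc), qual(sprintf('/gene="%s"', layout$name[i])))
    out <- c(out, fmt(kind, loc), qual(sprintf('/gene="%s"', layout$name[i])),
             qual(sprintf('/product="%s"', productOf(layout$name[i], kind))))
    if (kind == "CDS") {
      out <- c(out, qual("/codon_start=1"),
               qual(sprintf("/transl_table=%d", spec$geneticCode)))
      firstCDSDone <- firstCDSDone || !is.null(splitAt) || TRUE
    }
  }
  out <- c(out, "ORIGIN")
  lowSeq <- tolower(plusSeq)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunkEnd <- min(p + 59L, L)
    groups <- substring(lowSeq, seq(p, chunkEnd, by = 10L),
                        pmin(seq(p, chunkEnd, by = 10L) + 9L, chunkEnd))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  paste(out, collapse = "\n")
}

#' Generate a reproducible cohort of synthetic records
#'
#' Stands in for a mined corpus: generates \code{n} records from a common
#' template with per-record variation and optional planted group effects,
#' each with exact ground truth. Supported plantings:
#' \itemize{
#'   \item \code{asymmetry}: \code{"normal"} (plus strand A/C-rich) or
#'     \code{"reversed"} (the mirror composition: T/G-rich plus strand,
#'     i.e. reversed strand asymmetry).
#'   \item \code{urFractionRange}: per-record unassigned fraction drawn
#'     uniformly; since the gene complement is fixed, total length grows
#'     with the UR fraction, planting a positive length ~ UR\% coupling.
#'   \item \code{atCaiCoupling}: draws a per-record A+T target in
#'     \code{atRange} and couples it to an increasingly extreme
#'     within-family codon bias, planting a positive A+T ~ CAI coupling.
#'   \item \code{convention}: \code{"cox1_plus_minority"} (all genes on
#'     minus except cox1) or \code{"majority_plus"} (all genes on plus
#'     except cox1), the two annotation conventions the strand audit
#'     separates.
#' }
#'
#' @param n Number of records.
#' @param seed Integer seed; fixes the whole cohort (per-record seeds are
#'   drawn from it).
#' @param baseSpec Template \code{\link{genomeSpec}} supplying all
#'   parameters not varied here.
#' @param asymmetry NULL, \code{"normal"} or \code{"reversed"}.
#' @param urFractionRange NULL or length-2 numeric in [0, 1).
#' @param atCaiCoupling Logical; see above.
#' @param atRange A+T target range used when \code{atCaiCoupling}.
#' @param convention NULL, \code{"cox1_plus_minority"} or
#'   \code{"majority_plus"}.
#' @param group Group label stored in the truth table.
#' @param accessionPrefix Prefix for generated accessions.
#' @return List with \code{records} (list of \code{\link{generateGenome}}
#'   outputs), \code{texts} (character vector of GenBank records) and
#'   \code{truth} (data.frame, one row per record, with a \code{group}
#'   column).
#' @export
generateCohort <- function(n, seed = 1L, baseSpec = genomeSpec(),
                           asymmetry = NULL, urFractionRange = NULL,
                           atCaiCoupling = FALSE, atRange = c(0.62, 0.80),
                           convention = NULL, group = "A",
                           accessionPrefix = "MPC") {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  urf <- if (!is.null(urFractionRange))
    stats::runif(n, urFractionRange[1], urFractionRange[2]) else NULL
  atT <- if (atCaiCoupling) stats::runif(n, atRange[1], atRange[2]) else NULL
  records <- vector("list", n)
  for (i in seq_len(n)) {
    bw <- baseSpec$baseWeights
    if (!is.null(asymmetry)) {
      bw <- c(A = 0.30, C = 0.26, G = 0.17, T = 0.27)
      if (asymmetry == "reversed") bw <- c(A = bw[["T"]], C = bw[["G"]],
                                           G = bw[["C"]], T = bw[["A"]])
    }
    codonBias <- baseSpec$codonBias
    if (atCaiCoupling) {
      a <- atT[i]
      bw <- c(A = a * 0.53, C = (1 - a) * 0.60, G = (1 - a) * 0.40,
              T = a * 0.47)
      # left branch of the bias curve: higher A+T -> smaller b -> higher CAI
      codonBias <- 0.30 - 0.27 * (a - atRange[1]) / diff(atRange)
    }
    layout <- baseSpec$geneLayout
    if (!is.null(convention)) {
      layout$strand <- if (convention == "cox1_plus_minority") {
        ifelse(layout$name == "cox1", "+", "-")
      } else if (convention == "majority_plus") {
        ifelse(layout$name == "cox1", "-", "+")
      } else stop("unknown convention: ", convention)
    }
    spec <- genomeSpec(
      length = if (is.null(urf)) baseSpec$length else NULL,
      topology = baseSpec$topology,
      baseWeights = bw, geneLayout = layout,
      urFraction = if (is.null(urf)) 0.07 else urf[i],
      codonWeights = baseSpec$codonWeights, codonBias = codonBias,
      geneticCode = baseSpec$geneticCode, lineage = baseSpec$lineage,
      organism = sprintf("%s sp. %d", sub(" .*$", "", baseSpec$organism), i),
      accession = sprintf("%s%05d", accessionPrefix, i),
      wrap = baseSpec$wrap, splitFirstCDS = (i %% 7L == 0L),
      seed = seeds[i])
    records[[i]] <- generateGenome(spec)
  }
  truth <- do.call(rbind, lapply(records, `[[`, "truth"))
  truth$group <- group
  list(records = records,
       texts = vapply(records, `[[`, "", "text"),
       truth = truth)
}

#' Write a cohort to GenBank files plus a truth table
#'
#' @param cohort Result of \code{\link{generateCohort}}.
#' @param dir Output directory (created if needed).
#' @param perFile Records per GenBank file.
#' @return Invisibly, the paths written (truth table last, as
#'   \code{truth.csv}).
#' @export
writeCohort <- function(cohort, dir, perFile = 50L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(cohort$texts)
  splits <- split(seq_len(n), ceiling(seq_len(n) / perFile))
  paths <- character()
  for (k in seq_along(splits)) {
    p <- file.path(dir, sprintf("cohort_%03d.gb", k))
    writeLines(cohort$texts[splits[[k]]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(cohort$truth, tp, row.names = FALSE)
  invisible(c(paths, tp))
}
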