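# Independent oracles and fixture builders. These deliberately avoid the
# package's own interval/CAI/correlation code paths: coverage is checked
# per base, CAI by direct multiplication over codon occurrences, Spearman
# by explicit midranks + product-moment formula.

suppressMessages({
  library(Biostrings)
  library(S4Vectors)
})

# --- record construction -----------------------------------------------

makeFeatures <- function(rows) {
  if (!length(rows)) {
    ft <- S4Vectors::DataFrame(kind = character(), name = character(),
                               strand = character(), transl_table = integer(),
                               partial = logical())
    ft$intervals <- list()
    return(ft)
  }
  ft <- S4Vectors::DataFrame(
    kind = vapply(rows, `[[`, "", "kind"),
    name = vapply(rows, `[[`, "", "name"),
    strand = vapply(rows, `[[`, "", "strand"),
    transl_table = vapply(rows, function(r) as.integer(r$transl_table %||% NA),
                          NA_integer_),
    partial = vapply(rows, function(r) isTRUE(r$partial), NA))
  ft$intervals <- lapply(rows, `[[`, "intervals")
  ft
}

`%||%` <- function(a, b) if (is.null(a)) b else a

iv <- function(start, end, wraps = FALSE) {
  data.frame(start = as.integer(start), end = as.integer(end), wraps = wraps)
}

makeRecord <- function(seq, rows = list(), topology = "circular",
                       lineage = c("Eukaryota", "Opisthokonta", "Metazoa"),
                       geneticCode = 2L, accession = "TOY1") {
  new("GenomeRecord", accession = accession, definition = "toy record",
      organism = "Toyus toyus", sequence = Biostrings::DNAString(seq),
      topology = topology, topologyKnown = TRUE,
      features = makeFeatures(rows), lineage = lineage,
      geneticCode = as.integer(geneticCode))
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = "")

# random gene features on [0, L): mixtures of plain spans, abutting joins
# and (on circular records) origin-spanning intervals
randomFeatureRows <- function(L, n, circular) {
  rows <- list()
  for (i in seq_len(n)) {
    type <- sample(c("span", "join", if (circular) "wrap"), 1)
    strand <- sample(c("+", "-"), 1)
    if (type == "wrap") {
      s <- sample(seq_len(L - 1L), 1)          # 0-based start in [1, L-1]
      e <- sample(seq_len(max(1L, s - 1L)), 1) # end in [1, s-1] keeps len < L
      intervals <- iv(s, e, TRUE)
    } else {
      len <- sample(seq_len(max(2L, L %/% 3L)), 1)
      s <- sample(0:(L - len), 1)
      if (type == "join" && len >= 4L) {
        m <- s + sample(seq_len(len - 1L), 1)
        intervals <- rbind(iv(s, m), iv(m, s + len))
      } else {
        intervals <- iv(s, s + len)
      }
    }
    rows[[i]] <- list(kind = "gene", name = paste0("g", i), strand = strand,
                      intervals = intervals)
  }
  rows
}

# --- per-base UR oracle ------------------------------------------------

coveredOracle <- function(rows, L) {
  cov <- logical(L)
  for (r in rows) {
    t <- r$intervals
    for (k in seq_len(nrow(t))) {
      if (t$wraps[k]) {
        if (t$start[k] < L) cov[(t$start[k] + 1L):L] <- TRUE
        if (t$end[k] >= 1L) cov[1:t$end[k]] <- TRUE
      } else {
        cov[(t$start[k] + 1L):t$end[k]] <- TRUE
      }
    }
  }
  cov
}

# maximal UR runs from a coverage vector, with circular origin merge;
# returns a canonical character representation (sorted)
urOracle <- function(cov, circular) {
  L <- length(cov)
  ur <- !cov
  if (!any(ur)) return(character())
  r <- rle(ur)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(s = starts[r$values], e = ends[r$values]) # 1-based closed
  wraps <- rep(FALSE, nrow(runs))
  if (circular && nrow(runs) >= 1L && ur[1] && ur[L] && any(cov)) {
    first <- which(runs$s == 1L); last <- which(runs$e == L)
    if (length(first) == 1L && length(last) == 1L && first != last) {
      runs$s[last] <- runs$s[last]; runs$e[last] <- runs$e[first]
      wraps[last] <- TRUE
      runs <- runs[-first, , drop = FALSE]; wraps <- wraps[-first]
    }
  }
  out <- sprintf("%d:%d:%d", runs$s - 1L, runs$e, as.integer(wraps))
  sort(out)
}

canonicalUR <- function(urdf) {
  if (is.null(urdf) || nrow(urdf) == 0L) return(character())
  sort(sprintf("%d:%d:%d", urdf$start, urdf$end, as.integer(urdf$wraps)))
}

# --- brute-force CAI oracle -------------------------------------------

caiOracle <- function(codons, gcode) {
  aa <- gcode[codons]
  famSize <- table(gcode[gcode != "*"])
  keep <- aa != "*" & !is.na(aa) & famSize[aa] > 1
  codons <- codons[keep]
  if (!length(codons)) return(NA_real_)
  counts <- table(codons)
  prodW <- 1
  for (cd in codons) {
    fam <- names(gcode)[gcode == gcode[[cd]]]
    w <- counts[[cd]] / max(counts[intersect(fam, names(counts))])
    prodW <- prodW * w^(1 / length(codons))
  }
  prodW
}

# --- explicit-midrank Spearman oracle ----------------------------------

midrank <- function(v) {
  sv <- sort(v)
  vapply(v, function(x) mean(which(sv == x)), numeric(1))
}

spearmanOracle <- function(x, y) {
  a <- midrank(x); b <- midrank(y)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# rotate a circular sequence so that position `at` (0-based) becomes 1,
# used as the independent check for origin-spanning extraction
rotateSeq <- function(s, at) {
  L <- nchar(s)
  if (at == 0) return(s)
  paste0(substring(s, at + 1L, L), substring(s, 1L, at))
}
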