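#' Per-group summaries of portrait variables
#'
#' Median, first and third quartile, count and standard deviation of each
#' variable within each group, over non-missing values only (missing
#' values are never imputed). Groups with no rows are omitted with a
#' diagnostic message; a group whose values are all missing yields NA
#' summary cells with \code{n = 0}.
#'
#' @param x A \linkS4class{PortraitTable} or data.frame.
#' @param groupBy Name of the grouping column (e.g. \code{"major_group"}).
#' @param variables Numeric variable names to summarize; defaults to the
#'   numeric portrait variables.
#' @return data.frame with columns \code{group}, \code{variable},
#'   \code{n}, \code{median}, \code{q1}, \code{q3}, \code{sd}.
#' @export
groupSummary <- function(x, groupBy,
                         variables = c("length_bp", "n_genes", "su_skew",
                                       "at_content", "at_skew", "gc_skew",
                                       "cai", "ur_percent", "ur_at_content",
                                       "ur_median_length")) {
  df <- as.data.frame(x)
  stopifnot(groupBy %in% colnames(df), all(variables %in% colnames(df)))
  groups <- unique(df[[groupBy]])
  groups <- groups[!is.na(groups)]
  out <- list()
  for (g in groups) {
    sub <- df[df[[groupBy]] %in% g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      message("groupSummary: empty group '", g, "' omitted")
      next
    }
    for (v in variables) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = v, n = length(vals),
        median = if (length(vals)) stats::median(vals) else NA_real_,
        q1 = if (length(vals)) unname(stats::quantile(vals, 0.25)) else NA_real_,
        q3 = if (length(vals)) unname(stats::quantile(vals, 0.75)) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pairwise Spearman correlation matrix
#'
#' Tie-corrected Spearman rank correlations between all pairs of portrait
#' variables, on pairwise-complete observations. Two-sided p-values use
#' the t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on
#' \eqn{n - 2} degrees of freedom. Cells with fewer than 3 complete pairs
#' or a constant variable are NA. Non-significant cells are flagged by
#' \code{\link{significant}}, never hidden: both rho and p are always
#' reported so any threshold can be applied. No multiple-testing
#' correction is applied across the pairs.
#'
#' @param x A \linkS4class{PortraitTable} or data.frame.
#' @param variables Numeric columns to correlate.
#' @param alpha Significance threshold (default 0.05).
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
spearmanMatrix <- function(x,
                           variables = c("length_bp", "n_genes", "su_skew",
                                         "at_content", "at_skew", "gc_skew",
                                         "cai", "ur_percent", "ur_at_content",
                                         "ur_median_length"),
                           alpha = 0.05) {
  df <- as.data.frame(x)
  stopifnot(all(variables %in% colnames(df)))
  k <- length(variables)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n <- matrix(0L, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    rho[i, i] <- 1; n[i, i] <- sum(!is.na(df[[variables[i]]]))
    for (j in seq_len(i - 1L)) {
      xi <- df[[variables[i]]]; xj <- df[[variables[j]]]
      ok <- !is.na(xi) & !is.na(xj)
      st <- spearmanTest(xi[ok], xj[ok])
      rho[i, j] <- rho[j, i] <- st$rho
      p[i, j] <- p[j, i] <- st$p
      n[i, j] <- n[j, i] <- st$n
    }
  }
  methods::new("CorrelationMatrix", variables = variables, rho = rho,
               p = p, n = n, alpha = alpha)
}

#' Spearman rho and p for one pair
#'
#' @param x,y Numeric vectors of equal length (complete cases are used).
#' @return List with \code{rho}, \code{p} (two-sided, t approximation) and
#'   \code{n}; rho is NA for n < 3 or constant input.
#' @export
spearmanTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  nn <- length(x)
  if (nn < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = nn))
  r <- stats::cor(x, y, method = "spearman")
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((nn - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = nn - 2)
  }
  list(rho = r, p = p, n = nn)
}

#' Classify strand asymmetry from the two skews
#'
#' The common metazoan pattern ("normal") is a plus strand rich in A and
#' C: positive AT-skew and negative GC-skew. Reversed strand asymmetry
#' (RSA) is the opposite: more G than C and more T than A on the plus
#' strand (positive GC-skew, negative AT-skew). Same-sign pairs are
#' labelled \code{both_positive} / \code{both_negative}; any missing or
#' exactly zero skew gives \code{undefined}.
#'
#' @param at_skew,gc_skew Numeric vectors (recycled to common length).
#' @return Character vector with values in \code{normal}, \code{reversed},
#'   \code{both_positive}, \code{both_negative}, \code{undefined}.
#' @examples
#' rsaClassify(c(0.1, -0.2, 0), c(-0.3, 0.4, 0.1))
#' @export
rsaClassify <- function(at_skew, gc_skew) {
  nmax <- max(length(at_skew), length(gc_skew))
  a <- rep_len(as.numeric(at_skew), nmax)
  g <- rep_len(as.numeric(gc_skew), nmax)
  out <- rep("undefined", nmax)
  def <- !is.na(a) & !is.na(g) & a != 0 & g != 0
  out[def & a > 0 & g < 0] <- "normal"
  out[def & a < 0 & g > 0] <- "reversed"
  out[def & a > 0 & g > 0] <- "both_positive"
  out[def & a < 0 & g < 0] <- "both_negative"
  out
}

#' Normalized expansion profile
#'
#' Per-group median unassigned-region content and median length, each
#' normalized by the corresponding whole-table median, giving
#' dimensionless expansion/contraction ratios (a group identical to the
#' whole table maps to (1, 1)).
#'
#' @param x A \linkS4class{PortraitTable} or data.frame with columns
#'   \code{ur_percent} and \code{length_bp}.
#' @param groupBy Name of the grouping column.
#' @return data.frame with columns \code{group}, \code{n},
#'   \code{ur_ratio}, \code{length_ratio}.
#' @export
normalizedExpansion <- function(x, groupBy) {
  df <- as.data.frame(x)
  stopifnot(groupBy %in% colnames(df))
  gUR <- stats::median(df$ur_percent, na.rm = TRUE)
  gLen <- stats::median(df$length_bp, na.rm = TRUE)
  if (!is.finite(gUR) || gUR <= 0 || !is.finite(gLen) || gLen <= 0)
    stop("normalizedExpansion: whole-table median UR% and length must be > 0")
  groups <- unique(df[[groupBy]])
  groups <- groups[!is.na(groups)]
  out <- list()
  for (g in groups) {
    sub <- df[df[[groupBy]] %in% g, , drop = FALSE]
    if (!nrow(sub)) next
    out[[length(out) + 1L]] <- data.frame(
      group = g, n = nrow(sub),
      ur_ratio = stats::median(sub$ur_percent, na.rm = TRUE) / gUR,
      length_ratio = stats::median(sub$length_bp, na.rm = TRUE) / gLen,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Audit gene-strand annotation conventions
#'
#' Which strand a submitter calls "plus" is a convention, and mixed
#' conventions inside one clade flip the sign of both skews. For each
#' record the audit counts genes per strand and locates cox1 (identified
#' through the gene-name synonym table), since its position is commonly
#' taken as the reference for the plus strand. Records are classified as
#' \code{cox1_on_plus_minority} (cox1 on plus while most genes sit on
#' minus), \code{majority_on_plus} (most genes on plus while cox1 sits on
#' minus), \code{consistent} (cox1 on the majority strand) or
#' \code{indeterminate} (no cox1, conflicting cox1 copies, or a strand
#' tie).
#'
#' @param records List of \linkS4class{GenomeRecord}.
#' @param groups Optional character vector of group labels, one per
#'   record, used to tabulate the partition per group.
#' @return An \linkS4class{AuditReport}.
#' @export
strandConventionAudit <- function(records, groups = NULL) {
  if (is(records, "GenomeRecord")) records <- list(records)
  ng <- length(records)
  if (is.null(groups)) groups <- rep("all", ng)
  stopifnot(length(groups) == ng)
  rows <- lapply(seq_len(ng), function(i) {
    rec <- records[[i]]
    gs <- geneSet(rec)
    np <- sum(gs$strand == "+"); nm <- sum(gs$strand == "-")
    coxStrand <- {
      cs <- unique(gs$strand[normalizeGeneName(gs$name) == "cox1"])
      if (length(cs) == 1L) cs else NA_character_
    }
    majority <- if (np > nm) "+" else if (nm > np) "-" else NA_character_
    convention <- if (is.na(coxStrand) || is.na(majority)) {
      "indeterminate"
    } else if (coxStrand == majority) {
      "consistent"
    } else if (coxStrand == "+") {
      "cox1_on_plus_minority"
    } else {
      "majority_on_plus"
    }
    data.frame(accession = rec@accession, group = groups[i],
               n_plus = np, n_minus = nm, cox1_strand = coxStrand,
               majority_strand = majority, convention = convention,
               stringsAsFactors = FALSE)
  })
  recDf <- do.call(rbind, rows)
  part <- as.data.frame(table(group = recDf$group,
                              convention = recDf$convention),
                        stringsAsFactors = FALSE)
  names(part)[3] <- "count"
  methods::new("AuditReport", records = recDf, partition = part)
}
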