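# GenBank flat-file ingestion: header reading, location grammar,
# coordinate conversion, CDS extraction.

toyGb <- function(locus = "LOCUS       TOY001                  1000 bp    DNA     circular INV 01-JAN-2026",
                  featureLines = character(), L = 1000L, seq = NULL) {
  seq <- seq %||% strrep("ACGT", L / 4)
  seqLines <- vapply(seq(1L, nchar(seq), 60L), function(p) {
    chunk <- substring(seq, p, min(p + 59L, nchar(seq)))
    sprintf("%9d %s", p, tolower(chunk))
  }, "")
  paste(c(locus,
          "DEFINITION  Toyus toyus mitochondrion, complete genome.",
          "ACCESSION   TOY001",
          "SOURCE      mitochondrion Toyus toyus",
          "  ORGANISM  Toyus toyus",
          "            Eukaryota; Opisthokonta; Metazoa.",
          "FEATURES             Location/Qualifiers",
          featureLines, "ORIGIN", seqLines, "//"),
        collapse = "\n")
}

feat <- function(key, loc, ...) {
  c(sprintf("     %-16s%s", key, loc),
    vapply(c(...), function(q) paste0("                     ", q), ""))
}

test_that("LOCUS header gives topology and length; missing topology flags the record", {
  rec <- parseGenBank(toyGb(), text = TRUE)[[1]]
  expect_equal(topology(rec), "circular")
  expect_equal(seqLength(rec), 1000L)
  expect_false("AMBIGUOUS_TOPOLOGY" %in% validateRecord(rec))

  noTopo <- toyGb(locus = "LOCUS       TOY001                  1000 bp    DNA            INV 01-JAN-2026")
  rec2 <- parseGenBank(noTopo, text = TRUE)[[1]]
  expect_equal(topology(rec2), "linear")
  expect_true("AMBIGUOUS_TOPOLOGY" %in% validateRecord(rec2))
})

test_that("complement(join()) locations resolve to ordered minus-strand intervals", {
  gb <- toyGb(featureLines = feat("gene", "complement(join(100..200,300..400))",
                                  '/gene="nad5"'))
  rec <- parseGenBank(gb, text = TRUE)[[1]]
  ft <- features(rec)
  expect_equal(ft$strand, "-")
  expect_equal(ft$intervals[[1]]$start, c(99L, 299L))
  expect_equal(ft$intervals[[1]]$end, c(200L, 400L))
  expect_false(any(ft$intervals[[1]]$wraps))
})

test_that("origin-spanning join collapses to one wrapped interval with correct coverage", {
  gb <- toyGb(featureLines = feat("gene", "join(950..1000,1..50)", '/gene="rrnL"'))
  rec <- parseGenBank(gb, text = TRUE)[[1]]
  t <- features(rec)$intervals[[1]]
  expect_equal(nrow(t), 1L)
  expect_true(t$wraps)
  expect_equal(t$start, 949L)
  expect_equal(t$end, 50L)
  # per-base coverage count
  cov <- coveredOracle(list(list(intervals = t)), 1000L)
  expect_equal(sum(cov), 101L)
  expect_true(all(cov[950:1000]) && all(cov[1:50]) && !cov[51] && !cov[949])
})

test_that("partial markers are kept as printed and flagged", {
  gb <- toyGb(featureLines = feat("gene", "<100..>400", '/gene="cox1"'))
  rec <- parseGenBank(gb, text = TRUE)[[1]]
  ft <- features(rec)
  expect_true(ft$partial)
  expect_equal(ft$intervals[[1]], iv(99, 400), ignore_attr = TRUE)
  expect_true("PARTIAL_FEATURES" %in% validateRecord(rec))
})

test_that("malformed records and unresolvable features are skipped with diagnostics", {
  good <- toyGb(featureLines = feat("gene", "1..100", '/gene="cox1"'))
  noSeq <- paste(c("LOCUS       BAD001                   100 bp    DNA     linear INV 01-JAN-2026",
                   "DEFINITION  broken record.", "ACCESSION   BAD001", "//"),
                 collapse = "\n")
  recs <- parseGenBank(paste(good, noSeq, sep = "\n"), text = TRUE)
  expect_length(recs, 1L)
  dg <- attr(recs, "diagnostics")
  expect_equal(nrow(dg), 1L)
  expect_match(dg$reason, "ORIGIN|sequence")

  # descending span on a linear record cannot wrap: feature dropped, record kept
  gbBadFeat <- toyGb(
    locus = "LOCUS       TOY001                  1000 bp    DNA     linear  INV 01-JAN-2026",
    featureLines = c(feat("gene", "900..100", '/gene="bad"'),
                     feat("gene", "1..60", '/gene="trnF"')))
  recs2 <- parseGenBank(gbBadFeat, text = TRUE)
  expect_equal(nrow(features(recs2[[1]])), 1L)
  expect_equal(nrow(attr(recs2, "diagnostics")), 1L)
})

test_that("computability validation reports the documented issue codes", {
  trnaOnly <- makeRecord(randomSeq(200), list(
    list(kind = "tRNA", name = "trnF", strand = "+", intervals = iv(10, 80))))
  expect_equal(validateRecord(trnaOnly), "NO_CDS")

  bare <- makeRecord(randomSeq(200))
  expect_setequal(validateRecord(bare)[1:2], c("NO_GENES", "NO_CDS"))

  full <- parseGenBank(generateGenome(genomeSpec(seed = 3))$text, text = TRUE)[[1]]
  expect_length(validateRecord(full), 0L)
})

test_that("gene set falls back to span-deduplicated product features", {
  rows <- list(
    list(kind = "CDS", name = "cox1", strand = "+", intervals = iv(0, 90)),
    list(kind = "tRNA", name = "trnF", strand = "+", intervals = iv(100, 160)),
    list(kind = "tRNA", name = "trnF", strand = "+", intervals = iv(100, 160)),
    list(kind = "other", name = "misc", strand = "+", intervals = iv(0, 200)))
  rec <- makeRecord(randomSeq(200), rows)
  gs <- geneSet(rec)
  expect_equal(nrow(gs), 2L)               # duplicate span dropped, 'other' ignored
  expect_setequal(gs$name, c("cox1", "trnF"))

  # explicit gene features take precedence
  rows2 <- c(rows, list(list(kind = "gene", name = "cox1", strand = "+",
                             intervals = iv(0, 90))))
  expect_equal(nrow(geneSet(makeRecord(randomSeq(200), rows2))), 1L)
})

test_that("CDS extraction handles strands, joins and origin unwrapping", {
  s <- "ATGAAATTTCCC"
  plus <- makeRecord(s, list(list(kind = "CDS", name = "a", strand = "+",
                                  intervals = iv(0, 6))))
  expect_equal(as.character(extractCDS(plus)[[1]]), "ATGAAA")

  minus <- makeRecord(s, list(list(kind = "CDS", name = "a", strand = "-",
                                   intervals = iv(0, 6))))
  expect_equal(as.character(extractCDS(minus)[[1]]), "TTTCAT")

  # involution: minus-strand extraction == revcomp of the plus-strand slice
  set.seed(11)
  for (k in 1:20) {
    L <- sample(30:120, 1)
    sq <- randomSeq(L)
    a <- sample(0:(L - 9), 1)
    recP <- makeRecord(sq, list(list(kind = "CDS", name = "x", strand = "+",
                                     intervals = iv(a, a + 9))))
    recM <- makeRecord(sq, list(list(kind = "CDS", name = "x", strand = "-",
                                     intervals = iv(a, a + 9))))
    expect_equal(
      as.character(extractCDS(recM)[[1]]),
      as.character(Biostrings::reverseComplement(extractCDS(recP)[[1]])))
  }

  # origin-spanning CDS equals rotate-then-slice
  set.seed(12)
  for (k in 1:20) {
    L <- sample(60:200, 1)
    sq <- randomSeq(L)
    st <- sample((L - 20):(L - 1), 1)  # 0-based start near the end
    en <- sample(1:20, 1)
    rec <- makeRecord(sq, list(list(kind = "CDS", name = "w", strand = "+",
                                    intervals = iv(st, en, TRUE))))
    rotated <- rotateSeq(sq, st)
    expect_equal(as.character(extractCDS(rec)[[1]]),
                 substring(rotated, 1, (L - st) + en))
  }
})

test_that("coordinate round-trip: parsed intervals reproduce the printed base set", {
  set.seed(21)
  for (k in 1:40) {
    L <- sample(80:400, 1)
    circular <- sample(c(TRUE, FALSE), 1)
    rows <- randomFeatureRows(L, sample(1:5, 1), circular)
    # print locations, re-parse, compare per-base coverage feature by feature
    featureLines <- unlist(lapply(rows, function(r) {
      t <- r$intervals
      parts <- unlist(lapply(seq_len(nrow(t)), function(i) {
        if (t$wraps[i]) c(sprintf("%d..%d", t$start[i] + 1L, L),
                          sprintf("%d..%d", 1L, t$end[i]))
        else sprintf("%d..%d", t$start[i] + 1L, t$end[i])
      }))
      loc <- if (length(parts) > 1) paste0("join(", paste(parts, collapse = ","), ")")
             else parts
      if (r$strand == "-") loc <- paste0("complement(", loc, ")")
      feat("gene", loc, sprintf('/gene="%s"', r$name))
    }))
    topoTok <- if (circular) "circular" else "linear "
    gb <- toyGb(locus = sprintf("LOCUS       TOY001            %10d bp    DNA     %s INV 01-JAN-2026", L, topoTok),
                featureLines = featureLines, seq = randomSeq(L))
    rec <- parseGenBank(gb, text = TRUE)[[1]]
    ft <- features(rec)
    expect_equal(nrow(ft), length(rows))
    for (i in seq_along(rows)) {
      expect_equal(coveredOracle(list(list(intervals = ft$intervals[[i]])), L),
                   coveredOracle(rows[i], L))
      expect_equal(ft$strand[i], rows[[i]]$strand)
    }
  }
})

test_that("parsing the generator's output loses nothing", {
  g <- generateGenome(genomeSpec(seed = 77, splitFirstCDS = TRUE))
  rec <- parseGenBank(g$text, text = TRUE)[[1]]
  expect_equal(seqLength(rec), g$spec$length)
  expect_equal(topology(rec), g$spec$topology)
  expect_equal(as.character(lineage(rec)), g$spec$lineage)
  expect_equal(geneticCode(rec), g$spec$geneticCode)
  ft <- features(rec)
  expect_equal(sum(ft$kind == "gene"), nrow(g$spec$geneLayout))
  expect_equal(sum(ft$kind == "CDS"), sum(g$spec$geneLayout$kind == "CDS"))
  gs <- geneSet(rec)
  expect_equal(sum(gs$strand == "+"), g$truth$n_plus)
  expect_equal(sum(gs$strand == "-"), g$truth$n_minus)
})

test_that("location coordinates agree with an external reference parser", {
  gb <- generateGenome(genomeSpec(seed = 31, splitFirstCDS = TRUE))
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb$text, path)
  rec <- parseGenBank(path)[[1]]
  ft <- features(rec)
  ours <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA"), ]
  py <- sprintf(paste(
    "from Bio import SeqIO",
    "rec = next(SeqIO.parse(r'%s', 'genbank'))",
    "for f in rec.features:",
    "    if f.type in ('CDS','tRNA','rRNA'):",
    "        ps = ';'.join('%%d-%%d' %% (int(p.start), int(p.end)) for p in f.location.parts)",
    "        print(f.type, f.qualifiers['gene'][0], f.location.strand, ps)",
    sep = "\n"), path)
  out <- system2("python", "-", input = py, stdout = TRUE)
  expect_equal(length(out), nrow(ours))
  ref <- read.table(text = out, col.names = c("kind", "gene", "strand", "parts"))
  for (i in seq_len(nrow(ours))) {
    t <- ours$intervals[[i]]
    parts <- unlist(lapply(seq_len(nrow(t)), function(j) {
      if (t$wraps[j]) c(sprintf("%d-%d", t$start[j], seqLength(rec)),
                        sprintf("0-%d", t$end[j]))
      else sprintf("%d-%d", t$start[j], t$end[j])
    }))
    expect_equal(paste(parts, collapse = ";"), ref$parts[i])
    expect_equal(ours$strand[i], if (ref$strand[i] == 1) "+" else "-")
    expect_equal(ours$name[i], ref$gene[i])
  }
})
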