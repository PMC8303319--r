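# The eleven per-genome variables: skews, contents, strand usage,
# unassigned regions, CAI.

test_that("AT/GC-skew and A+T content match direct counts, with NA for empty denominators", {
  expect_equal(atSkew("ATAT"), 0)
  expect_equal(atSkew("AATC"), 1 / 3)
  expect_true(is.na(atSkew("GGCC")))
  expect_equal(gcSkew("GCGC"), 0)
  expect_equal(gcSkew("GGGC"), 0.5)
  expect_true(is.na(gcSkew("ATTA")))
  expect_equal(atContent("ATGC"), 50)
  expect_equal(atContent("AAAT"), 100)

  set.seed(101)
  for (k in 1:50) {
    s <- randomSeq(sample(10:500, 1))
    n <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    expect_equal(atSkew(s), unname((n["A"] - n["T"]) / (n["A"] + n["T"])))
    expect_equal(gcSkew(s), unname((n["G"] - n["C"]) / (n["G"] + n["C"])))
    expect_equal(atContent(s) + 100 * (n["G"] + n["C"]) / sum(n), 100,
                 ignore_attr = TRUE)
    expect_gte(1, abs(atSkew(s))); expect_gte(1, abs(gcSkew(s)))
  }
})

test_that("reverse-complementing the genome negates both skews exactly", {
  set.seed(102)
  for (k in 1:25) {
    s <- Biostrings::DNAString(randomSeq(sample(20:300, 1)))
    rc <- Biostrings::reverseComplement(s)
    expect_identical(atSkew(rc), -atSkew(s))
    expect_identical(gcSkew(rc), -gcSkew(s))
  }
  # ambiguity codes are excluded from numerator and denominator
  expect_equal(atSkew("AANNTC"), 1 / 3)
  expect_equal(atContent("ATNN"), 100)
})

test_that("strand-usage skew is |n+ - n-| / total over the gene set", {
  expect_equal(strandUsageSkew(c(rep("+", 7), rep("-", 3))), 0.4)
  expect_equal(strandUsageSkew(rep("-", 5)), 1)
  expect_true(is.na(strandUsageSkew(character())))
})

test_that("unassigned regions: worked linear and circular cases", {
  # linear 100 bp, genes on [0,40) and [60,100) -> single UR [40,60)
  rec <- makeRecord(randomSeq(100), list(
    list(kind = "gene", name = "a", strand = "+", intervals = iv(0, 40)),
    list(kind = "gene", name = "b", strand = "-", intervals = iv(60, 100))),
    topology = "linear")
  ur <- unassignedRegions(rec)
  expect_equal(canonicalUR(ur), "40:60:0")
  m <- computeMetrics(rec)
  expect_equal(m$ur_percent, 20)
  expect_equal(m$ur_median_length, 20)

  # circular 100 bp, single gene [20,80): flanking gaps merge into one wrap UR
  rec2 <- makeRecord(randomSeq(100), list(
    list(kind = "gene", name = "a", strand = "+", intervals = iv(20, 80))))
  ur2 <- unassignedRegions(rec2)
  expect_equal(nrow(ur2), 1L)
  expect_equal(canonicalUR(ur2), "80:20:1")
  expect_equal(ur2$width, 40L)

  # same layout on a linear record: two distinct URs
  rec3 <- makeRecord(randomSeq(100), list(
    list(kind = "gene", name = "a", strand = "+", intervals = iv(20, 80))),
    topology = "linear")
  expect_equal(canonicalUR(unassignedRegions(rec3)), c("0:20:0", "80:100:0"))

  # full tiling -> no URs, percent 0, median missing
  rec4 <- makeRecord(randomSeq(100), list(
    list(kind = "gene", name = "a", strand = "+", intervals = iv(0, 100))))
  expect_equal(nrow(unassignedRegions(rec4)), 0L)
  m4 <- computeMetrics(rec4)
  expect_equal(m4$ur_percent, 0)
  expect_true(is.na(m4$ur_median_length))
})

test_that("UR extraction equals the per-base coverage oracle on randomized records", {
  set.seed(103)
  for (k in 1:120) {
    L <- sample(40:500, 1)
    circular <- sample(c(TRUE, FALSE), 1)
    rows <- randomFeatureRows(L, sample(1:6, 1), circular)
    rec <- makeRecord(randomSeq(L), rows,
                      topology = if (circular) "circular" else "linear")
    ur <- unassignedRegions(rec)
    cov <- coveredOracle(rows, L)
    expect_identical(canonicalUR(ur), urOracle(cov, circular))
    # conservation: UR bases + covered bases == length
    expect_equal(sum(ur$width) + sum(cov), L)
  }
})

test_that("CAI: forced and closed-form cases", {
  code2 <- Biostrings::getGeneticCode("2")
  # one codon per family -> every w = 1 -> CAI exactly 1
  g <- generateGenome(genomeSpec(seed = 5, codonBias = 0,
                                 geneLayout = compactGeneLayout(),
                                 length = 1200L))
  rec <- parseGenBank(g$text, text = TRUE)[[1]]
  expect_equal(g$truth$cai, 1)
  expect_equal(cai(rec), 1)

  # single two-codon family used 3:1 -> (1/3)^(1/4)
  counts <- c(AAA = 3, AAG = 1)  # Lys family under the standard code
  expect_equal(caiFromCounts(counts, Biostrings::getGeneticCode("1")),
               (1 / 3)^(1 / 4))

  # stop codons and single-codon families carry no signal
  expect_equal(caiFromCounts(c(AAA = 3, AAG = 1, TAA = 50, TGG = 7),
                             Biostrings::getGeneticCode("1")),
               (1 / 3)^(1 / 4))
  expect_true(is.na(caiFromCounts(c(TAA = 2, TGG = 1),
                                  Biostrings::getGeneticCode("1"))))
})

test_that("CAI matches the brute-force oracle and is invariant to CDS order", {
  codes <- c("1", "2", "5")
  set.seed(104)
  for (k in 1:100) {
    gcode <- Biostrings::getGeneticCode(sample(codes, 1))
    nonstop <- names(gcode)[gcode != "*"]
    codons <- sample(nonstop, sample(3:30, 1), replace = TRUE)
    expect_equal(caiFromCounts(table(codons), gcode),
                 caiOracle(codons, gcode), tolerance = 1e-12)
  }

  # reordering the CDS features leaves CAI unchanged
  g <- generateGenome(genomeSpec(seed = 6))
  rec <- parseGenBank(g$text, text = TRUE)[[1]]
  ft <- features(rec)
  idx <- sample(seq_len(nrow(ft)))
  rec2 <- rec
  rec2@features <- ft[idx, ]
  expect_identical(cai(rec), cai(rec2))
})

test_that("codons with ambiguity codes are skipped, not fatal", {
  s <- paste0("ATG", "AAA", "ANA", "AAG", "TAA")
  rec <- makeRecord(s, list(list(kind = "CDS", name = "x", strand = "+",
                                 intervals = iv(0, nchar(s)),
                                 transl_table = 1L)), geneticCode = 1L)
  rec@geneticCode <- 1L
  # counted codons: ATG (single family, dropped), AAA, AAG, TAA (stop, dropped)
  expect_equal(cai(rec), (1 / 1 * 1 / 1)^0.5 * 1)  # both Lys codons used once -> w = 1
})

test_that("compute_all populates exactly the computable fields", {
  # tRNA-only record: gene metrics present, CAI missing
  rec <- makeRecord(randomSeq(300), list(
    list(kind = "tRNA", name = "trnF", strand = "+", intervals = iv(10, 80)),
    list(kind = "tRNA", name = "trnV", strand = "-", intervals = iv(120, 190))))
  m <- computeMetrics(rec)
  expect_equal(m$n_genes, 2L)
  expect_false(is.na(m$ur_percent))
  expect_false(is.na(m$su_skew))
  expect_true(is.na(m$cai))
  expect_match(m$flags, "NO_CDS")

  # unannotated record: every annotation-dependent field missing
  bare <- makeRecord(randomSeq(300))
  mb <- computeMetrics(bare)
  expect_equal(mb$n_genes, 0L)
  expect_true(all(is.na(mb[c("su_skew", "cai", "ur_percent", "ur_at_content",
                             "ur_median_length")])))
  expect_false(is.na(mb$at_skew))  # composition never needs annotation
})
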