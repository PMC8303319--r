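---
title: "Mitochondrial genome portraits: methods and design"
author: "MitoPortrait authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial genome portraits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoPortrait)
```

## The problem

Complete mitochondrial genomes are deposited in GenBank by thousands of
independent groups, with heterogeneous annotation practice. Comparative
"portrait" analyses summarize each chromosome by a small set of
compositional and architectural descriptors and then aggregate them by
clade. MitoPortrait implements such a pipeline end to end: GenBank
flat-file ingestion, per-genome metrics, lineage placement, clade
aggregation, strand-asymmetry classification, and an audit of
strand-annotation conventions. Because a corpus-scale download is neither
reproducible nor desirable in a package, a synthetic-record generator
with analytic ground truth accompanies every stage.

## The eleven per-genome variables

For each record the pipeline computes:

1. **length** (bp) and **topology** (circular/linear), read directly from
   the LOCUS line;
2. **number of annotated genes**, counted over the *gene set* (below);
3. **|SU-skew|**, the strand-usage skew $|n_+ - n_-|/(n_+ + n_-)$ over the
   gene set;
4. **A+T content** (%), $100\,(A+T)/(A+C+G+T)$ over unambiguous bases of
   the deposited plus strand;
5. **AT-skew** $(A-T)/(A+T)$ and **GC-skew** $(G-C)/(G+C)$ on the plus
   strand, so that an excess of A (resp. G) is positive;
6. **CAI**, a self-referential codon adaptation index (below);
7. **UR%**, **UR A+T content** and **UR median length** over unassigned
   regions: maximal stretches covered by no gene-set feature.

A variable is missing exactly when its computability constraint fails: at
least one annotated gene is required for |SU-skew| and the UR metrics, at
least one CDS for CAI. Records carrying only tRNAs therefore have no CAI;
unannotated records keep only length, topology and the composition
descriptors. Missing values are never imputed anywhere downstream.

### The gene set

GenBank records annotate genes inconsistently: some carry explicit
`gene` features, others only `CDS`/`tRNA`/`rRNA` product features. The
gene set is the `gene` features when any exist, otherwise the union of
product features deduplicated by identical span (strand plus interval
list). This single rule feeds the gene count, |SU-skew|, UR coverage and
the strand audit, so all four stay mutually consistent.

### Coordinates and circularity

Internally all intervals are 0-based half-open; GenBank's 1-based
inclusive locations are converted on ingestion. `complement(...)`,
`join(...)`/`order(...)` and `complement(join(...))` are resolved into
ordered interval lists; a join whose consecutive segments abut across the
origin of a circular record collapses into a single interval flagged
`wraps`, covering $[start, L) \cup [0, end)$. Unassigned regions are the
complement of the merged gene-set coverage; on circular records the two
gaps flanking the origin merge into one origin-spanning region, so a
region is never split in two by an arbitrary coordinate origin.
Mixed-strand joins (per-segment complements, as in trans-spliced plant
genes) are not resolved; such features are dropped with a diagnostic.

### The self-referential CAI

The classical codon adaptation index scores a gene against a reference
set of highly expressed genes. No such reference exists uniformly across
all eukaryotes, so the index here is *self-referential*: codon counts are
pooled over all in-frame codons of all CDSs of the record (trailing
partial codons and ambiguous codons dropped), the relative adaptiveness
of codon $c$ is $w(c) = n(c)/\max_{c' \in fam(c)} n(c')$ within its
synonymous family under the record's genetic code, and

$$\mathrm{CAI} = \Big(\prod_{i=1}^{N} w(c_i)\Big)^{1/N}$$

over all $N$ counted codons. Stop codons and single-codon families carry
no usage information and are excluded. The genetic code is resolved as:
CDS `/transl_table` qualifier (modal value over the record's CDSs), then
the record-level code, then the standard code (id 1); code tables come
from `Biostrings::getGeneticCode`. Note that a perfectly uniform usage
and a fully collapsed usage (one codon per family) both give CAI = 1;
intermediate imbalance gives values below 1. The index measures
*unevenness structure*, not expression adaptation.

### Assumptions worth stating

* The exact strand-usage skew formula is not fixed by any convention we
  could adopt verbatim; the definition above is the natural gene-count
  analog of the base skews and only its absolute value is reported. This
  is an assumption of this implementation.
* Skews are computed on the entire deposited plus strand, not on coding
  regions only: they are whole-genome descriptors here.
* Topology is read, never inferred; a LOCUS line without a topology token
  defaults to linear and flags `AMBIGUOUS_TOPOLOGY`.
* Partial locations (`<`, `>`) are used as printed and flagged
  `PARTIAL_FEATURES`; no repair of defective annotations is attempted.
* Multi-record files are parsed record-wise with no chromosome merging,
  so multipartite genomes appear as independent rows.

## Taxonomy placement

Placement is case-insensitive keyword matching of the record's own
ORGANISM lineage against a plain-text rule table
(`inst/extdata/subdivision_rules.tsv`), with the deepest matched clade
deciding among **Amorphea** (Amoebozoa, Opisthokonta including Fungi and
Metazoa), **Diaphoretickes** (Archaeplastida including Viridiplantae,
Excavata, Haptista, and the SAR clade) and **CRuMs**; viruses and
prokaryotes map to `non_eukaryote` and are excluded from aggregations,
anything unmatched to `incertae_sedis`. Two notes: Excavata is placed
inside Diaphoretickes, following the grouping scheme this pipeline
mirrors rather than the more common treatment of Excavata as its own
supergroup; and Excavata lineages are also matched via "Discoba", the
name NCBI lineage strings actually use. Matching the record's own
lineage string (rather than querying a live taxonomy service) keeps the
pipeline fully offline; the rank map is therefore best-effort and sparse.
Viridiplantae lineages are additionally graded along the water-to-land
transition (Chlorophyta, non-embryophyte Streptophyta, non-vascular
Embryophyta, Tracheophyta) for expansion profiles.

## Aggregation and inference

* **Group summaries**: median, quartiles (type-7), count and standard
  deviation per group and variable, over non-missing values. The median
  of an even-count UR list is the mean of the two central values.
* **Spearman matrices**: tie-corrected rank correlation (midranks) on
  pairwise-complete observations; two-sided p-values from the t
  approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$. Cells with fewer than
  3 complete pairs or a constant variable are NA. The significance
  threshold defaults to $\alpha = 0.05$; both $\rho$ and $p$ are always
  reported so any other threshold can be applied, and no multiple-testing
  correction is applied across the variable pairs — flagged
  significance is descriptive, not confirmatory.
* **Strand-asymmetry classes**: `normal` (AT-skew > 0, GC-skew < 0, the
  common metazoan pattern of an A/C-rich plus strand), `reversed`
  (GC-skew > 0 and AT-skew < 0), `both_positive`/`both_negative` for
  same-sign pairs, `undefined` for missing or exactly zero skews. Zero
  is deliberately not assigned a side: a zero skew carries no direction.
* **Expansion profiles**: per-group median UR% and median length, each
  normalized by the whole-table median; refused when a whole-table
  median is zero.
* **Strand audit**: per record, gene counts per strand and the strand of
  cox1 (located through a gene-name synonym table: cox1 = COI = CO1,
  cytb = cob, nad = ND, atp = ATPase, ...). Records split into
  `cox1_on_plus_minority` (cox1 on plus, most genes on minus — the
  "cox1 defines the plus strand" convention), `majority_on_plus` (most
  genes on plus, cox1 on minus — the "majority defines the plus strand"
  convention), `consistent`, and `indeterminate` (no cox1, conflicting
  cox1 copies, or a strand tie; ties are never broken arbitrarily).

## The synthetic-data generator

`genomeSpec()`/`generateGenome()` emulate the corpus structure the
pipeline was built for: circular (or linear) chromosomes; a realistic
gene complement (default: 13 protein-coding genes with the standard
bilaterian names, 2 rRNAs, 22 tRNAs, most genes on the plus strand, the
vertebrate mitochondrial code); controllable per-strand base composition
(default plus strand A/C-rich: AT-skew $\approx +0.05$, GC-skew
$\approx -0.21$, A+T $\approx 57\%$ — magnitudes typical of vertebrate
mitogenomes); controllable codon usage within synonymous families;
a target unassigned fraction (default 7%, giving $\approx 16.5$ kb
records); origin-spanning genes or gaps; joined CDS locations; embedded
lineage strings and `/transl_table` qualifiers.

Ground truth is computed from the *realized* record by construction-time
bookkeeping — exact counts, not distribution parameters — and
independently of the parsing and metric code under test, so round-trip
checks need no sampling tolerances (exact for count ratios, $10^{-12}$
for CAI, which is the only floating-point chain). CDSs are synthesized
codon-wise: a forced ATG start, body codons drawn from the codon-weight
model with stop codons excluded, and a TAA stop. In the geometric
within-family bias model, ATG is kept at rank 1 of its family so that
`codonBias = 0` realizes exactly one codon per family and forces
CAI = 1.

Planted cohort effects used by the tests and the acceptance script:

* **asymmetry**: mirroring the base weights (A↔T, G↔C) flips both skew
  signs, planting reversed strand asymmetry;
* **length–UR coupling**: varying the UR fraction over a fixed gene
  complement couples total length to UR%;
* **A+T–CAI coupling**: the A+T target is tied to an increasingly
  extreme within-family codon bias. Because the self-referential CAI is
  1 at both usage extremes, the coupling deliberately samples one
  monotone branch of the bias–CAI curve (bias $0.3 \to 0.03$ as A+T
  rises) so that the planted correlation has a defined sign;
* **convention mixing**: per-cohort gene-strand layouts realize the two
  annotation conventions the audit separates.

What the generator does *not* emulate: evolutionary sequence divergence,
gene-order evolution, introns and trans-splicing, control-region
structure, heteroplasmy, or annotation errors beyond the malformed-record
fixtures built directly in the tests. Passing round-trip and recovery
tests therefore demonstrates correctness of the computations and the
planted-signal logic, not robustness to every pathology of real GenBank
records.

## Numerical and degenerate-input choices

* Zero denominators (no A/T bases, no G/C bases, no genes, no eligible
  codons) yield NA, never errors.
* CAI is accumulated in log space; the equality against the brute-force
  product oracle is asserted at $10^{-12}$.
* Genes tiling the whole sequence give UR% = 0 with a missing UR median
  (a median of an empty set is not 0).
* An empty or unmatched lineage places the record in `incertae_sedis`
  rather than failing; rule-table edits can never crash placement.
* Malformed records and unresolvable features are skipped with logged
  diagnostics; the pipeline log accounts for every input record
  (accepted + discarded = seen).

## Problem sizes

The test suite exercises randomized records up to 500 bp against
per-base oracles (100+ cases per property), a 200-record round-trip
cohort on a compact ~0.8 kb gene layout, 50+50-record asymmetry-recovery
cohorts and a 1000-record end-to-end run at the realistic ~16.5 kb
default. The acceptance script recomputes its quantities on cohorts of
80–200 records. These sizes were chosen to exercise every code path —
circular and linear, wrapped and joined, both strands — while keeping a
full run comfortably interactive.

## Known limitations

* The parser supports the location grammar that mitochondrial records
  actually use; nested or mixed-strand compound locations are rejected
  (with diagnostics) rather than resolved.
* Taxonomic ranks beyond a few anchor ranks are not resolved offline;
  the subdivision and group labels are the reliable columns.
* Ecology columns are schema placeholders; populating them requires an
  external trait service and is out of scope.
* Entrez retrieval is out of scope; the pipeline starts from flat files
  on disk.
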