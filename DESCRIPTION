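Package: MitoPortrait
Title: Compositional and Architectural Portraits of Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Parses annotated mitochondrial genome records in GenBank
    flat-file format and computes a per-genome "portrait" of eleven
    compositional and architectural variables: sequence length, topology,
    annotated gene count, strand-usage skew, A+T content, AT-skew, GC-skew,
    a self-referential codon adaptation index, and the percentage, A+T
    content and median length of unassigned (intergenic) regions, with
    full support for joined, complemented and origin-spanning feature
    locations on circular chromosomes. Places each record into the major
    eukaryotic subdivisions from its lineage string, aggregates portraits
    into clade summaries, Spearman correlation matrices and strand-asymmetry
    classes, and audits gene-strand annotation conventions against the
    position of cox1. A synthetic-record generator with analytic ground
    truth makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, Annotation, SequenceMatching, Phylogenetics
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'MitoPortrait-package.R'
    'analysis.R'
    'genbank-io.R'
    'metrics.R'
    'portrait.R'
    'synthetic-data.R'
    'taxonomy.R'
    'utils-intervals.R'
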