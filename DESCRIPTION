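Package: ovamir
Title: Two-Library Small RNA Sequencing Analysis of Ovarian miRNAs
Version: 0.1.0
Authors@R:
    person("ovamir", "maintainers", email = "ovamir@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully synthetic-data-driven reimplementation of a
    classic two-library small RNA sequencing study design: read cleaning with
    per-category accounting, priority-rule annotation of unique tags, known
    miRNA quantification with tags-per-million normalization, the
    Audic-Claverie exact count test for two-library differential expression,
    hairpin-based novel miRNA prediction with a built-in secondary-structure
    folding dynamic program, seed-region target prediction against 3' UTRs,
    hypergeometric GO/pathway enrichment with Bonferroni and
    Benjamini-Hochberg correction, and qPCR delta-Ct validation. A
    synthetic-data generator emits a complete toy study (genome, annotation,
    references, FASTQ libraries, UTRs, term maps, CT table) with a
    machine-readable truth record so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    ape,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
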