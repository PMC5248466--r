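Package: pitmobilome
Title: Proteomics-Informed-by-Transcriptomics Analysis of Transposable
    Element Proteins and Genome Annotation Completeness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis for proteomics informed by transcriptomics
    (PIT) experiments in non-model organisms. Extracts open reading frames
    from de novo assembled transcriptomes by six-frame translation, groups
    peptide evidence into protein groups, classifies proteins by a tiered
    homology cascade against reference proteomes, identifies transposable
    element (TE) proteins against curated TE databases with calibrated
    identity and coverage thresholds, normalises TE protein counts against
    genomic representation to measure relative enrichment, and evaluates
    genome annotation completeness by transcript-to-genome triage,
    sequencing-gap scanning and chromosomal hotspot detection. Includes a
    deterministic synthetic-data generator producing genome, transcriptome,
    peptide-evidence and TE-database fixtures with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
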