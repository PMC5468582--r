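Package: mirhunt
Title: Homology-Based Plant miRNA Discovery, Target Prediction and
    Sex-Locus Candidate Mapping from Transcriptome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers conserved microRNAs in sex-separated plant
    transcriptome (EST) collections by homology to a reference set of
    mature miRNAs, validates candidate precursors with a
    hairpin-restricted folding score and plant pre-miRNA criteria
    (AMFE/MFEI, stem-arm placement, star-strand mismatches), predicts
    miRNA targets by complementarity expectation scoring, quantifies
    per-sex target expression as transcripts per million (TPM), and
    flags gender-locus candidate genes that sit in a configured
    sex-determination interval, are regulated by a sex-specific miRNA,
    and are expressed in a single sex. Includes a seeded synthetic-data
    generator with a truth table so every stage is testable end to end
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
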