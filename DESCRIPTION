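Package: tfcensus
Title: Genome-Wide Census and Jasmonate-Responsiveness Analysis of
    AP2/ERF Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification and
    classification of AP2/ERF-superfamily transcription factors:
    position-specific scoring matrix (PSSM) domain scanning with exact
    p-values, domain-architecture family assignment (AP2, RAV, DREB,
    ERF, Soloist), neighbour-joining phylogeny with bootstrap anchoring
    to labelled references, exon-intron structure statistics, ZOOPS-EM
    motif discovery, reciprocal-best-hit orthology with Smith-Waterman
    alignment, FPKM-based methyl-jasmonate responsiveness calling, and
    qPCR (2^-ddCt) and dual-luciferase assay statistics. Includes a
    synthetic-genome generator with known truth labels so every stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
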