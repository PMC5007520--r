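Package: genefam
Title: Genome-Wide Gene Family Characterization on Synthetic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the classic genome-wide
    gene-family survey: domain-profile identification of family members
    (with empirically calibrated e-values), progressive multiple alignment
    and neighbor-joining phylogeny with bootstrap support and
    reference-guided subfamily assignment, exon/intron categorization and
    ZOOPS expectation-maximization motif discovery, tandem and collinear
    (segmental) duplication detection, Nei-Gojobori Ka/Ks estimation with
    duplication dating, and FPKM/qPCR expression classification. A
    first-class synthetic-data module plants ground truth (domains, tandem
    clusters, collinear blocks, codon divergence at known omega and Ks,
    expression classes, delta-delta-Ct fold changes) so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
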