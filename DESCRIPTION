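Package: hgtEvidence
Title: Evidence Pipeline for Horizontal Gene Transfer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects horizontally transferred genes by combining five
    independent lines of evidence: degenerate signature-motif scanning of
    protein sequences, the alien index computed from donor and recipient
    best-hit E values, G+C compositional affinity of a candidate gene for
    its putative donor versus its host genome, congruence between the
    best homology hit and the nearest neighbour in a gene phylogeny, and
    proximity of mobile genetic elements within fixed flanking windows of
    the focal gene. Includes a deterministic synthetic-data generator
    that builds complete transfer scenarios (genomes, genes, homology
    tables, trees, element annotations) with known truth labels, and a
    pipeline that aggregates per-gene verdicts into a tabular report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Genetics, SequenceMatching, Software
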