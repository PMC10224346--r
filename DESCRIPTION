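Package: cetamt
Title: Metallothionein Gene Mining and Cluster Architecture in Cetacean Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects metallothionein (MT)-like coding regions in genomic
    contigs, delineates the canonical three-exon/two-intron mammalian MT gene
    model by spliced alignment against reference coding sequences, classifies
    the four isoforms (Mt1-Mt4), reconstructs Mt4-Mt3-Mt2-Mt1 cluster
    architecture with intergenic-region statistics, and clusters coding
    sequences with Kimura two-parameter distances and neighbor-joining trees
    with bootstrap support. Ships transcriptions of published cetacean MT
    cluster measurements and a synthetic-genome simulator with ground-truth
    annotations so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
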