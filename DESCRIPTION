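Package: lantimine
Title: In Silico Mining of Type 1 Lantibiotic Gene Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Homology-driven discovery of type 1 lantibiotic (lanthipeptide)
    biosynthetic gene clusters in annotated bacterial genomes. Screens
    proteomes with LanB (lanthionine dehydratase) and LanC (lanthionine
    cyclase) driver sequences under BLAST-like E-value and identity
    thresholds, discovers unannotated LanA precursor genes by six-frame
    translation of intergenic DNA with a leader/propeptide composition
    heuristic, assembles and classifies gene clusters (complete, lanA-less,
    orphan), merges frameshift-split dehydratase genes, computes
    reference-anchored motif conservation over multiple alignments, and
    groups enzymes into phylogroups with neighbor-joining trees. Includes a
    synthetic-genome generator with planted clusters and full ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SequenceMatching, GenomeAnnotation, Phylogenetics
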