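Package: nanotax
Title: Barcoded Full-Length 16S Nanopore Amplicon Simulation,
    Demultiplexing and Taxonomic Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for dual-barcoded full-length 16S
    rRNA amplicon sequencing workflows on long-read (nanopore-style)
    data. Simulates barcoded amplicon reads with a configurable
    substitution/insertion/deletion error model and a ground-truth
    sidecar; filters reads on length and error-probability-averaged
    quality; demultiplexes pooled reads by single (1BC) or double (2BC)
    12-bp PCR barcodes with IUPAC-aware primer localization and
    trimming; estimates species-level relative abundances by
    expectation-maximization over read-to-reference alignment
    likelihoods; computes pool efficiency, sample purity calls,
    positive predictive value, Cramer's V and Theil's U concordance
    statistics, alpha diversity, Bray-Curtis dissimilarity, PERMANOVA
    and rarefaction; and builds per-sample consensus sequences via
    greedy centroid clustering and majority vote, pairwise-identity
    distance matrices, neighbor-joining trees and bootstrap supports
    with newick output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Microbiome, Sequencing, Metagenomics, Classification,
    Phylogenetics
RoxygenNote: 7.3.3
Collate: 
    'nanotax-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'annotate-em.R'
    'consensus.R'
    'core-io.R'
    'demux.R'
    'diversity.R'
    'filter.R'
    'metrics.R'
    'phylo.R'
    'sequence-utils.R'
    'simulate.R'
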