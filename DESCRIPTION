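Package: chromarch
Title: Chromatin Architecture from Hi-C Contact Maps and Locus-Level Features
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of higher-order chromatin organisation.
    Implements iterative correction (ICE) of binned intrachromosomal Hi-C
    contact maps, A/B compartment eigenvector calling on chromosome arms,
    two-state hidden Markov model segmentation of compartment profiles,
    directionality-index topological domain (TAD) boundary calling,
    boundary feature-enrichment statistics with Mann-Whitney tests and
    Bonferroni control, random-forest prediction of compartment
    eigenvectors from chromatin features with out-of-bag evaluation,
    permutation variable importance and cross-cell-type transfer,
    structural-variability analysis across cell types, and clustering of
    TADs into functional classes. Ships a synthetic-genome generator with
    planted compartments, TADs, feature tracks, biases and annotations so
    every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
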