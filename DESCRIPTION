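Package: NLRmotifs
Title: Motif Prediction and Analysis for Plant NLR Immune Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-residue machine-learning prediction of the conserved sequence
    motifs of plant nucleotide-binding leucine-rich-repeat (NLR) immune
    receptors. Provides a registry of 17 motif classes spanning the CC, TIR,
    NBS and LRR domains, evolutionary per-residue features from an iterative
    profile (PSSM) search against a focused homolog database, sliding-window
    multilayer-perceptron motif classifiers with cross-validated evaluation,
    rule-based post-processing (motif calling, satellite resolution, NBS
    layout validation, LRR repeat-ladder delineation and NLR classification),
    downstream motif analytics (excised-motif chimeras, identity clustering,
    relative-entropy profiles, physico-chemical OPTICS clustering of LRR
    motifs) and Henikoff-weighted mutual-information coevolution analysis,
    together with fully seeded synthetic-data generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
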