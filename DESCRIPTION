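Package: replitimer
Title: Replication Timing Profiling, Segmentation and Chromatin Context Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-fraction Repli-seq replication timing (RT) analysis
    in binned genomes: CPM normalization and pseudocounted log2(E/L) RT
    profiles with genomic-span loess smoothing, Gaussian hidden-Markov-model
    segmentation of RT into early/mid/late states with an E-like/L-like split
    of the mid state, Hi-C A/B compartment analysis (matrix balancing,
    observed/expected, correlation-matrix eigenvectors, saddle plots),
    replication initiation-site consensus, zone clustering and fold-change
    classification, summit-centered signal matrices with k-means site
    clustering, and transcription-stratified RT mode-shift analysis. A
    coupled synthetic-data generator with known ground truth (planted RT
    domains, compartment plaid, transcription and origin strengths, plus
    perturbation scenarios) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
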