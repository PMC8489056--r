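Package: refstab
Title: Reference-Gene Stability Analysis and Relative Quantification for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for selecting stable reference genes from RT-qPCR
    quantification-cycle (Cq) data and for reference-normalized relative
    quantification. Implements four stability algorithms (comparative
    delta-Cq, geNorm with pairwise-variation selection of the optimal number
    of reference genes, NormFinder's variance decomposition, and BestKeeper
    descriptive statistics and index correlations), a geometric-mean-of-ranks
    consensus, dilution-series standard curves with amplification-efficiency
    estimation, between-run correction, and 2^-ddCq fold-change analysis.
    Includes small open-reading-frame and protein-motif utilities and a
    seeded Cq-data simulator with known variance components for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
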