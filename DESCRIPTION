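Package: protrate
Title: Time-Normalized Protein Divergence Across Mammalian Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for multi-locus
    orthologous protein sets, built around the ten-subunit CatSper channel
    in therian mammals. Reads per-locus protein alignments, concatenates
    them in a fixed subunit order into a partitioned supermatrix, estimates
    pairwise amino-acid distances (p-distance, Poisson and gamma
    corrections, pairwise or complete deletion), normalizes distances by
    TimeTree-style divergence times (100 MY = 1) to compare
    lineage-specific evolutionary rates between clades (ANOVA with Tukey
    HSD), builds neighbor-joining trees with bootstrap bipartition support,
    simulates multi-locus protein evolution along a time tree under a
    20-state Markov model with per-branch rate multipliers for end-to-end
    validation, and scans sequences for IQ-like calmodulin-binding motifs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
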