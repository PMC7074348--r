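Package: cytobalance
Title: Cytonuclear Transcriptional Coordination Analysis for Plant Polyploids
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how nuclear, plastid and mitochondrial transcriptional
    outputs respond to whole-genome duplication from gene-level RNA-seq count
    tables. Provides TPM normalization, ERCC spike-in based expression per
    genome copy, compartment-level stoichiometry ratios (targeted fractions,
    organelle/nuclear bulk ratios, balance ratios), interaction-tier
    coefficient-of-variation summaries, chimeric-complex correlations, a
    self-contained nonparametric/parametric statistics battery
    (Kruskal-Wallis, Dunn with Benjamini-Hochberg, one-way ANOVA,
    Bonferroni-corrected t tests, least-squares regression), delta-delta-Cq
    qPCR relative copy-number estimation, and a fully specified tri-genome
    count simulator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
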