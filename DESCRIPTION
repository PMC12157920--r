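Package: lofproxy
Title: Graded Loss-of-Function Proxy Analysis for Strain-Panel Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Treats natural expression variation of a focal gene across a
    genetically diverse strain panel as a dose-proxy for loss of function.
    Stratifies strains into high- and low-expression groups, screens the
    transcriptome for genes correlated with the focal gene (Pearson, with
    Benjamini-Yekutieli false-discovery control), scores gene sets on the
    low-minus-high log2 fold-change ranking with a weighted
    Kolmogorov-Smirnov running-sum enrichment statistic and a hypergeometric
    over-representation test, quantifies transcription-factor correlation
    shifts between strata (Fisher z), and classifies pathway convergence
    between the panel contrast and a true-knockout contrast. Includes a
    synthetic strain-panel generator that plants known coupling structure so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
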