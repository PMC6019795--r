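Package: heteropath
Title: Detection of Bidirectionally Perturbed Tissue-Specific Pathways
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene sets ("pathways") that are heterogeneously
    perturbed in one tissue relative to a virtual median cell built from all
    tissues, by summing absolute per-gene t-statistics over fold-change-passing
    set members and assessing significance by phenotype-label permutation with
    Benjamini-Hochberg control of the false discovery rate. Includes minimal
    parametric (average fold-change) and weighted Kolmogorov-Smirnov
    enrichment comparators, a linear additive microarray simulator with an
    ANOVA-based power and type-I-error study harness, an ROC/AUC evaluation
    protocol with permutation significance, and a promoter motif-enrichment
    stage (MATCH-style matrix and core similarity scores over position weight
    matrices) feeding tissue-specific transcription-factor regulatory network
    construction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
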