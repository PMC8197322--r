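Package: mirpanel
Title: Reference-Gene Selection, Normalization and Differential Expression
    for TaqMan miRNA Array Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cycle-threshold (Ct) data from custom TaqMan
    OpenArray miRNA panels, as used in CRISPR knockout cell-line studies.
    Implements a detection filter requiring amplification in every sample,
    housekeeping-miRNA selection by a modified Bianchi procedure (expression
    level, Mann-Whitney group stability, coefficient-of-variation and outlier
    screens, and iterative correlation with the geometric-mean reference),
    delta-Ct normalization and fold-change estimation, empirical-Bayes
    moderated-t differential expression with Storey (2002) q-value FDR
    estimation, hypergeometric over-representation analysis of miRNA target
    genes against pathway tables, and treatment-response assay mathematics
    (clonogenic plating efficiency and survival fractions, Annexin/PI apoptosis
    normalization, four-parameter logistic IC50 fitting, and total-protein
    densitometry normalization). A seeded synthetic-data generator emulates the
    statistical structure of such panels so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
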