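Package: gliapanel
Title: Targeted Panel Transcriptomics of Amyloid-Associated Glial Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for NanoString-style targeted expression panels
    profiling glial responses to amyloid pathology under a 2x2 factorial design.
    Reads lane-level RCC count files, performs system and limit-of-detection QC,
    background thresholding from negative controls, geNorm housekeeping-gene
    selection and normalization to a log2 expression matrix; per-gene
    differential expression with Benjamini-Hochberg correction and principal
    component summaries; first-principal-component pathway scoring; directed and
    undirected global significance scores for gene sets; cell-type profiling by
    marker-gene averaging with a random-gene-set permutation QC; curation and
    composite scoring of seven amyloid-associated glial transcriptomic
    signatures (PIGs, OLIGs, DAM, HM, MGnD, M0, DAA); two-way factorial ANOVA
    with Fisher's PLSD pairwise comparisons; and a negative-binomial lane
    simulator emulating a 770-gene neuropathology panel so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
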