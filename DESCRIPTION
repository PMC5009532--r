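Package: dcsig
Title: Differential Coexpression Subtyping and Prognostic Signature Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for discovering compact prognostic
    transcription-factor signatures from two-condition expression data:
    differential coexpression analysis (DCG scoring and DCL classification
    with permutation significance), differential regulation analysis (TED and
    TDD ranking of transcription factors, differentially regulated links),
    seed-gene assembly, nonnegative matrix factorization consensus clustering
    with cophenetic model-order selection, Kaplan-Meier/log-rank prognosis
    stratification and per-gene Cox hazard ratios, cross-cohort signature
    distillation with a random-signature baseline and drug-target enrichment,
    and subtype-specific regulatory-network inference by stepwise linear
    regression. Includes synthetic cohort generators with planted structure
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
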