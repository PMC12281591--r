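Package: sigscreen
Title: Connectivity Screening of Transcriptomic Signatures by Bidirectional
    Preranked GSEA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Matches a differential-expression signature against libraries of
    perturbation signatures (LINCS L1000-style z-score profiles, level 5).
    Implements preranked gene set enrichment analysis with the weighted
    running-sum statistic, a gene-set permutation null, and sign-stratified
    normalized enrichment scores (NES); a bidirectional connectivity screen
    that scores each perturbation's top and bottom extreme gene sets against a
    query ranking and ranks perturbations by summarized NES (up-set NES minus
    down-set NES); hypergeometric over-representation analysis with mean-rank
    aggregation across libraries; Jaccard similarity of differential gene
    sets; footprint-based pathway activity scoring by weighted sums with a
    gene-permutation null; reporter-metabolite aggregation of gene-level
    significance over gene-metabolite networks; readers and writers for
    TSV/GCT/GMT formats; and a synthetic-data generator that plants mimic,
    inverter and decoy signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
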