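Package: miRpair
Title: Integrative Paired Tumor/Normal microRNA-mRNA-Protein-Copy-Number Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for matched tumor/normal
    expression cohorts built around benign smooth-muscle tumors and their
    patient-matched normal tissue. Implements paired SAM-style differential
    expression with sign-flip permutation FDR, consensus microRNA target
    prediction across two predictor tables with direction-stratified
    inverse-association sets and hypergeometric enrichment, aCGH loss/gain
    segment calling under explicit probe-count, fold-change and score
    criteria with minimal common regions across patients, and net
    immunoscore analysis of ordinal immunohistochemistry data. A seeded
    synthetic-cohort generator with known ground truth (differential
    features, miRNA-target repression, deletions over miRNA loci, ordinal
    protein scores) makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
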