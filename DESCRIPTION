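Package: nogcss
Title: Germline Variant Network Signatures for Tumor Recurrence Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tumor recurrence risk from germline genomic
    information. Classifies germline variants from paired tumor/normal
    variant allele frequencies, diffuses each patient's functionally
    mutated genes over a recurrence signaling network to per-gene
    heating scores, discovers 30-gene network-operational (NOG)
    signatures per cancer hallmark by randomized survival screening,
    and combines them into a vote-based combinatory signature set
    (NOG_CSS) that calls patients low risk, high risk, or unpredicted.
    Includes Kaplan-Meier / log-rank and Cox covariate evaluation, a
    21-gene Oncotype DX recurrence-score comparator, leukocyte
    metagene group comparisons, and a synthetic cohort generator so
    the whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    withr
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
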