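Package: beeallele
Title: Allele-Specific Expression and Methylation Analysis Without Parental Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide calling of allele-specific expression (ASE) and
    allele-specific DNA methylation (ASM) in diploid samples for which no
    parental genomes are available. Starting from per-SNP allelic read counts,
    genes are tested for allelic imbalance with an allele-allocation rule and a
    quasibinomial logistic regression; starting from bisulfite epireads,
    allelically methylated regions are detected with a sliding-window
    two-model (single-profile vs. 50:50 epiallele mixture) likelihood-ratio
    caller. Includes gene-level weighted methylation, hypergeometric set
    overlap and GO enrichment, rank-based group comparisons, and seeded
    synthetic-data generators that emulate overdispersed allelic counts and
    epiallele mixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
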