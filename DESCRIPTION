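Package: dfbf
Title: Bayesian Detection and Quantification of Introgression on Four-Taxon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies introgression between taxa on the classic
    four-taxon (ABBA-BABA) configuration using a conjugate-Beta Bayesian model
    selection approach. Per-window posterior shape parameters yield a
    fraction-of-introgression estimate (df-theta) and a Bayes-factor-style
    evidence measure (df-BF) interpreted on Jeffreys' scale, alongside the
    comparator statistics df, Patterson's D, fd and Dp. Includes a
    sliding-window genome scanner for FASTA alignments and VCF variant calls,
    a four-taxon coalescent simulator with a gene-flow pulse for validation
    experiments, and ggplot2 visualisations of scan results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    Biostrings,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
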