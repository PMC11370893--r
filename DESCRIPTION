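Package: gutsig
Title: Cross-Study Analysis of Disease-Associated Gut Microbiome Signature Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compiling disease-associated gut microbiome signature
    species across meta-analyses, classifying each species' typical body site
    from multi-body-site relative-abundance profiles, annotating species with
    bacteremia and aerotolerance status, and testing enrichment of these
    properties between disease-enriched and disease-depleted species with
    exact 2x2 inference (two-sided Fisher p-values and conditional
    maximum-likelihood odds ratios). Includes a synthetic-data generator for
    site-structured compositional abundance matrices, meta-study signature
    tables, and annotation tables with planted effect sizes, so every stage
    of the pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
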