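Package: beenet
Title: Co-Activity Network Analysis of the Honeybee Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying dysbiosis of the honeybee (Apis mellifera)
    gut microbiota under pesticide exposure and bacterial supplementation.
    Builds signed co-activity networks from 16S rRNA transcript count tables
    (Spearman rank correlation with exact permutation p-values at small
    replicate numbers, Benjamini-Hochberg gating, effect-size thresholding),
    compares network topology (degree, closeness centrality, neighborhood
    connectivity) across experimental conditions with Kruskal-Wallis and Dunn
    post hoc tests, assigns taxonomy from BLAST-style hit tables (top-hit
    identity rule with lowest-common-ancestor fallback), tests differential
    taxon activity with a negative-binomial Wald test on median-of-ratios
    normalized counts, and estimates Kaplan-Meier survival with log-rank group
    comparisons for cage-cohort mortality data. Includes a Gaussian-copula
    negative-binomial simulator that emulates the replicate structure of
    caged-bee experiments so every analysis stage can be exercised end to end
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
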