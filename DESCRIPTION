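Package: rhizonet
Title: Co-Occurrence and Phenotype-Taxon Network Analysis for Rhizosphere
    Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline from taxon-by-sample amplicon count
    tables and sample phenotypes to microbial co-occurrence networks,
    condition-specific topology summaries, phenotype-taxon networks and
    composite-centrality node prioritization. Includes cumulative sum scaling
    normalization, alpha-diversity estimators (Chao1, Shannon, Simpson,
    Pielou), Bray-Curtis/Euclidean/Jaccard dissimilarities, block-constrained
    PERMANOVA, SIMPER decomposition, core/unique-taxon membership, Spearman and
    Pearson association networks with FDR gating, a ten-metric topology suite
    (Walktrap modularity, Kleinberg hub scores, discrete power-law degree
    fits), lasso/GLM phenotype-taxon network assembly, and a seeded synthetic
    community generator with planted correlation and effect structure for
    end-to-end validation.
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
    glmnet,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
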