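Package: clockfindr
Title: Transcriptome Reduction and Bait-Based Identification of Circadian
    Clock Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for reducing de novo transcriptome
    assemblies to representative gene catalogs and identifying circadian
    clock protein candidates by bait-based pairwise orthology. Includes
    pair-synchronized read quality filtering, six-frame single-best ORF
    prediction with completeness classification, greedy near-duplicate
    clustering at an identity/coverage threshold, longest-isoform selection
    per Trinity gene, assembly statistics (N50, retention, complete-ORF
    fraction), best-hit annotation merging, a four-stage Pfam/PANTHER
    vetting cascade for ortholog candidates, workflow validation
    statistics, deterministic domain-architecture diagrams, and a
    ground-truthed synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
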