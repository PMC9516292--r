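Package: netfx
Title: Network-Effect Scoring of Differentially Expressed Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of RNA-Seq differential expression over a
    weighted gene association network. Parses cuffdiff-style '.diff' tables,
    filters differentially expressed genes by fold change and q-value, maps
    mouse symbols to human orthologs, scores every network gene by a one-step
    weighted sum of differential-expression node weights (the network-effect
    score), extracts the influenced subnetwork at an edge-weight cutoff,
    decomposes it into dense clusters by simulated annealing on weighted
    modularity, and ranks pathways by mean member score together with
    hypergeometric enrichment of top-scored genes. Includes in-silico PCR and
    consensus/PWM promoter motif scanning utilities, and a synthetic-data
    generator with ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
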