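Package: apmicro
Title: Longitudinal Case-Control Analysis of the Infant Gut Microbiome in
    Allergic Proctocolitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strain-resolved, longitudinal case-control analysis of
    infant gut metagenomes, motivated by food protein-induced allergic
    proctocolitis (AP). Provides cohort modelling (age binning, disease-state
    sample subsets, optimal one-to-one age matching, demographic contingency
    tests), community metrics (Chao1, Shannon, Bray-Curtis and Aitchison
    distances, principal coordinates analysis, longitudinal stability),
    a self-contained multivariable differential-abundance model on
    arcsine-square-root transformed proportions with Benjamini-Hochberg
    correction, MinHash genome sketching with Mash-formula distances and
    stratified relatedness comparisons, neighbour-joining strain trees from
    marker SNVs or pangenome gene content, a phylogenetic clade
    disease-enrichment scan with clade-unique gene extraction and term
    enrichment, MAG quality tiering, a random-forest classification protocol
    with leakage-safe feature elimination and permutation attribution, and a
    fully parameterised synthetic cohort generator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    clue,
    jsonlite,
    randomForest,
    Rcpp,
    vegan
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
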