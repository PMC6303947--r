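Package: subfamkit
Title: Enzyme Subfamily Classification from Consensus Phylogenetic Clades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying an enzyme family into subfamilies defined as
    clades that are supported above a threshold and appear consistently across
    independently inferred phylogenetic trees. Includes exact pairwise alignment
    with Karlin-Altschul statistics for homolog collection, seed-anchored
    alignment extension, gap-fraction trimming and conservation profiling,
    Poisson-corrected distances with neighbor-joining and bootstrap supports,
    sequence-level functional annotation (cofactor-specificity fingerprints,
    catalytic-triad checks, motif search), active-site contact mapping on
    macromolecular coordinates, kinetics aggregation (kcat/KM), a synthetic
    family simulator providing ground truth for every stage, and a
    knowledgebase exporter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d,
    withr
Config/testthat/edition: 3
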