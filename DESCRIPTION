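Package: dhmap
Title: Dendritic Heat Maps of Genotype and Phenotype Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds dendritic heat maps (DHMs): radial figures whose
    concentric rings show the same DNA sequence set clustered at a ladder of
    fractional-identity cutoffs (0.75 to 1.00 by 0.01), with each cluster
    coloured by the log-ratio of two phenotype group abundances so that
    genotype divergence (cluster branching) can be read together with
    phenotype divergence (heat map response). Includes simulators for a
    mutating sequence lineage and an exponentially growing mutate-and-
    duplicate population with group-evening restart policies, agglomerative
    minimum/maximum/average-linkage and divisive greedy centroid clustering,
    count-proportional radial layout with parent-span conservation, a
    23-category diverging colour model, and SVG plus Circos-format output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
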