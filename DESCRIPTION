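Package: splitbias
Title: Quantifying Over-Optimism in Unsupervised Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the over-optimism bias that arises when many method
    combinations for unsupervised microbiome analysis (taxon clustering, hub
    detection, differential association-network analysis, and sample
    clustering) are tried on the same data and only the best result is
    reported. The package draws repeated disjoint discovery/validation
    sample splits, enumerates grids of normalization, association,
    sparsification and clustering choices, selects the best-performing
    combination on the discovery half, re-evaluates it on the validation
    half, and summarizes the validation-minus-discovery differences.
    Includes synthetic count-data generators with planted association
    blocks, hub taxa, group-specific network structure and latent sample
    clusters, plus the full evaluation toolbox (adjusted Rand index,
    silhouette widths, centrality-based hub detection, graphlet correlation
    distance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    graphics,
    igraph,
    jsonlite,
    mvtnorm,
    Rcpp,
    splines,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    biomformat,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
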