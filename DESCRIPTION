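Package: nipevo
Title: Comparative Analysis of Metabolic Networks of Interacting Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds networks of interacting pathways (NIPs) from taxon-level
    pathway/metabolite annotations, where vertices are metabolic pathways and
    edges link pathways sharing metabolites, weighted by the number of shared
    metabolites. Quantifies each NIP with a 52-descriptor suite covering
    degree, distance, centrality and clique structure plus Shannon-type
    information indices, discriminates groups of taxa by supervised
    classification (accuracy, Cohen's kappa, minimal feature subsets), and
    tests per-pathway frequency, connectivity and centrality shifts between
    groups with exact and rank-based statistics under multiple-testing
    correction. Includes a seeded generator of KEGG-style synthetic
    annotation datasets with plantable group effects so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    nnet,
    rpart,
    randomForest,
    e1071,
    class,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
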