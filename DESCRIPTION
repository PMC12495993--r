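Package: panelcraft
Title: Multi-View Characterization and Genetic-Algorithm Design of Targeted Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes gene panels for targeted spatial transcriptomics across five
    metric categories - feature specificity (gene specificity scores, panel entropy,
    variation recovery, cell-type classification), feature diversity (Spearman redundancy),
    biological inference (pathway over-representation, Jaccard-pruned pathway diversity,
    ligand/receptor composition), spatial information (Moran's I, nearest-neighbor
    correlation) and forward compatibility (perturbation impact behind a pluggable model
    contract) - and optimizes panels with an elitist genetic algorithm over a multi-metric
    objective. Includes a seeded negative-binomial single-cell/spatial simulator so every
    metric is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ggplot2,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    generics,
    jsonlite,
    withr,
    ranger,
    fgsea,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
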