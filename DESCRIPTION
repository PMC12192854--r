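Package: allonet
Title: Allosteric Network Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping allosteric communication in multidomain
    protein kinases from conformational ensembles. From C-alpha coordinate
    ensembles the package computes flexibility descriptors (RMSD, RMSF,
    delta-RMSF, representative medoid structures), essential-dynamics PCA,
    dynamic cross-correlation matrices (DCCM), correlation-network
    communities with module purity and integration modules, betweenness
    centrality, Shrake-Rupley solvent-accessible surface area and
    delta-SASA interface detection, and an interface-weighted allosteric
    hub score. A random-forest state classifier with SMOTE rebalancing and
    Gini/permutation importance separates active-like from inactive-like
    ensembles from interpretable geometric features. A synthetic-ensemble
    generator with planted correlation structure makes every stage testable
    without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    broom,
    cluster,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
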