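Package: smdin
Title: Sample Mass-Difference Networks for Untargeted Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds mass-difference networks (MDiNs) from high-accuracy
    untargeted metabolomics feature lists and derives per-sample subnetworks
    (sMDiNs) whose graph properties serve as sample profiles for clustering
    and classification. Edges connect neutral masses differing by the exact
    monoisotopic mass of a chemical transformation (mass-difference-based
    building block, MDB) within a ppm tolerance. Six profiling metrics are
    provided (degree, betweenness and closeness centrality, MDB impact,
    weighted MDB impact, and graphlet-correlation GCD-11 features), together
    with an intensity-based pretreatment baseline (imputation, reference or
    probabilistic quotient normalization, generalized log, Pareto scaling),
    clustering and classifier evaluation harnesses with dedicated performance
    statistics, and a synthetic data generator with planted transformation
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    mclust,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, Network, MassSpectrometry, Classification,
    Clustering, GraphAndNetwork
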