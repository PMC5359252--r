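Package: latentconn
Title: Latent Differential Connectivity Network Detection for Two-Group
    Connectome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects latent subnetworks of a functional connectome whose
    edges are collectively enriched in group differences. Per-edge two-sample
    t-tests on Fisher-Z connectivity matrices yield a weighted evidence graph
    W = -log(p); greedy seed-and-grow extraction finds clique-topology
    candidate networks and a Kernighan-Lin style relabeling finds k-partite
    readings; network-level significance controlling whole-graph multiplicity
    comes from a max-statistic permutation test over subject group labels.
    Includes a synthetic connectome generator with planted clique and
    k-partite differential networks for calibration and power studies, plus
    reporting (heatmap reordering, directional edge tables) and SVM
    leave-one-out classification of detected-network features.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
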