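Package: calcitrace
Title: Classification and Explainable Analysis of Single-Cell Calcium
    Imaging Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell calcium-imaging time series
    (GCaMP delta-F/F0 traces) from ligand-stimulation experiments:
    simulation of labelled synthetic cohorts with group-specific response
    amplitude, latency, responder fraction and basal dynamics; windowed
    trace quantification (total change, area under the curve, inactive-cell
    fractions, group mean traces and peaks); 2D embeddings (PCA, an exact
    t-SNE with recorded Kullback-Leibler objective, UMAP), Lloyd K-means
    with silhouette scoring and cluster-composition tables; a benchmark
    suite of classical classifiers plus a feature-learning feedforward
    network trained with dropout, Adam and early stopping; hidden-layer
    feature embeddings and transfer evaluation of pharmacologically rescued
    cells; and Grad-CAM-style per-frame saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pracma,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr
Suggests:
    cluster,
    tidyr,
    yaml,
    optparse,
    Rtsne,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
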