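Package: esconn
Title: Effective Connectivity Analysis for Intracranial Stimulation iEEG and fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for effective-connectivity mapping with direct
    electrical brain stimulation. Quantifies stimulation-locked intracranial
    evoked potentials (trial rejection, baseline normalization, early/late
    component range, latency and significance), decodes the stimulation site
    from response features and from waveform manifold embeddings, estimates
    nonparametric spectral conditional Granger causality via Wilson spectral
    matrix factorization with phase-randomized surrogate significance, and
    analyses block-design stimulation fMRI at region level (spline
    deconvolution, residual partial-correlation networks, edge contrasts,
    consensus community detection, run classification). A synthetic-data
    module generates evoked-potential trials, vector-autoregressive segments
    and BOLD runs with known ground truth so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    signal,
    igraph,
    xgboost,
    randomForest,
    pROC,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
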