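Package: ideoconn
Title: Connectome-Based Prediction of Political Ideology from Functional
    Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting a continuous ideology phenotype from
    functional connectivity (FC) matrices built from ROI-averaged BOLD
    time series. Implements task-signal regression and Pearson FC
    construction with missing-ROI exclusion, a connectome regression
    network with edge-to-node and node-to-graph layers trained under
    Euclidean loss with out-of-fold scoring, correlation and principal
    component analyses of the score matrix, Monte Carlo cross-validated
    comparison of logistic models against survey benchmarks, L1-penalized
    variable importance, and gradient-based saliency mapping of
    predictive edges aggregated to anatomical regions. Includes a
    synthetic-data generator with planted edge-phenotype associations so
    every stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, glmnet, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
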