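Package: graynet
Title: Modularity and Gray Nodes in Cortical Thickness Covariance Networks
Version: 0.1.0
Authors@R:
    person("pSoBid", "Network Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction of binary structural covariance networks from
    subject-by-region cortical thickness tables (covariate residualization,
    Pearson correlation, one-sided FDR thresholding), Newman spectral
    modularity with Q-threshold-controlled recursive division, an extended
    ternary modularity that identifies "gray nodes" shared between
    overlapping modules, degree-matched random-graph null ensembles with
    Monte-Carlo mean and standard-deviation curves, pooled two-sample
    cohort statistics, seeded synthetic-cohort and toy-graph generators,
    and a command-line interface binding the pipeline together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
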