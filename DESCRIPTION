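Package: neurogbn
Title: Gaussian Bayesian Networks for Comparing Neuron Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns Gaussian Bayesian networks from per-cell feature tables
    (electrophysiology and dendritic morphometry) with score-based tabu
    search over the BIC, stabilises structures with bootstrap arc-confidence
    blacklisting, derives precision matrices and partial correlations from
    the fitted networks, and compares groups of cells (e.g., species) via
    the closed-form Hellinger distance between the implied multivariate
    Gaussians with parameter re-fitting. Includes an SWC morphometry module
    computing nine per-arbor dendritic features and a fully seeded
    synthetic-data generator (random linear-Gaussian DAGs, ancestral
    sampling, toy SWC fixtures) so that every stage is testable against
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
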