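Package: scrlearn
Title: Trial-Level Modelling of Skin Conductance Responses in Pavlovian
    Threat Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the computational analysis of Pavlovian
    threat-conditioning experiments indexed by skin conductance responses
    (SCRs). Provides pseudorandomized trial-schedule generation with block
    and reinforcement constraints; trough-to-peak SCR scoring of continuous
    electrodermal traces; hierarchical Bayesian Rescorla-Wagner models of
    acquisition, extinction and a unified emotional learning state, fit by
    Hamiltonian Monte Carlo with non-centered parameterization and
    split-Rhat convergence diagnostics; one-dimensional cluster-based
    permutation tests with threshold-free cluster enhancement; and bespoke
    summary statistics (differential scores, time bins, SCR similarity
    indices, subjective-ratings contrasts). A synthetic-data generator
    emulates the within-participant active/sham stimulation design and
    produces trial tables and raw 500-Hz traces with known ground truth for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
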