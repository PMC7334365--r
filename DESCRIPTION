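Package: netcog
Title: Structural Brain Network Efficiency and Longitudinal Cognitive Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking white matter structural
    connectomes to longitudinal cognitive decline in cerebral small vessel
    disease. Implements deterministic FACT-style streamline tractography on
    tensor-field phantoms, construction of volume-normalized weighted 90-node
    connectomes from streamline endpoints, a panel of 21 binary and weighted
    graph-theoretic network measures including degree-preserving null-model
    normalized efficiencies, composite cognitive z-scores, elastic-net
    selection of the most predictive network measure, and linear mixed-effects
    modelling of cognitive change with likelihood-ratio testing. A synthetic
    cohort generator emulates the statistical structure of a small vessel
    disease cohort (small-world connectomes, lesion-linked covariates,
    informatively truncated three-visit trajectories) so that every stage of
    the analysis is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    glmnet,
    lme4,
    MASS,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
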