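Package: nodalmap
Title: Observer-Independent Mapping and Density Estimation of Nodal Recurrence Patterns
Version: 0.1.0
Authors@R:
    person("nodalmap", "developers", email = "nodalmap@example.org", role = c("aut", "cre"))
Description: Tools for patterns-of-failure analysis of pelvic lymph-node
    metastases in radiotherapy. Maps lymph-node center points into a common
    template anatomy via displacement vector fields, estimates the
    patient-equally-weighted three-dimensional probability density of nodal
    involvement (per-mille per cubic centimeter) with a rectangular-kernel
    density estimator and Gaussian smoothing, quantifies intra-patient versus
    cohort-level spatial clustering of metastases, and computes level-wise
    involvement statistics: binary frequencies, Fisher exact subgroup tests
    with Bonferroni adjustment, and volume-normalized relative proportions
    with BCa bootstrap inference against a homogeneous-distribution
    reference. Includes a synthetic-cohort generator with smooth per-patient
    deformation fields and a synthetic nodal-level atlas so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
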