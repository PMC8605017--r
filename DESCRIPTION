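Package: ctdnaJM
Title: Joint Modelling of Longitudinal ctDNA and Recurrence for MRD Surveillance
Version: 0.1.0
Authors@R:
    person("ctdnaJM", "Developers", email = "ctdnajm@example.org", role = c("aut", "cre"))
Description: Tumor-informed minimal residual disease (MRD) calling from
    UMI-consensus read-family tables (single-strand and duplex consensus
    building, background-error polishing, ctDNA positivity), landmark
    survival analyses (Kaplan-Meier, log-rank, Cox proportional hazards,
    lead-time testing), and joint models of longitudinal log ctDNA level
    with time-to-recurrence for resected non-small cell lung cancer.
    Includes individualized dynamic prediction of conditional
    recurrence-free probabilities, censoring-aware time-dependent AUROC and
    prediction-error metrics with repeated cross-validation, and a
    synthetic-cohort generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    splines,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
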