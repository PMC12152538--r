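Package: morphocov
Title: Structural Covariance Networks and CSF Biomarker Group Analysis of Regional Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for relating regional brain volumes to
    cerebrospinal-fluid amyloid and tau biomarker status. Provides A/T
    biomarker group assignment from Abeta42/40 ratio and p-Tau181 cutoffs,
    volume preprocessing (quality-control filtering, session averaging,
    intracranial-volume normalisation, bilateral merging), group-level
    structural covariance networks with graph-theoretic metrics and
    non-parametric group comparisons, a standardized global clustering
    coefficient (SGCC) for cluster separability of labelled embeddings,
    per-region logistic association with Firth and ridge variants and
    bootstrap AUROC, random-effects (REML) meta-analysis across cohorts
    with false-discovery-rate correction, and Dice/spin-test
    correspondence between significant-region maps and reference network
    partitions. A seeded synthetic-cohort generator emulates the study
    conditions so every stage is testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    tools,
    utils,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    metafor,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
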