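#!/usr/bin/env Rscript
# Stage 1: generate the synthetic session-level cohort and the spherical
# parcellation used by the spatial correspondence stage.
#
# The generator's defaults encode the emulated study conditions: four CSF
# biomarker groups (control 60, A+T- 25, A+T+ 121, other dementia 100),
# group-specific age distributions, block-structured volume covariance
# that is strongest in controls and weakest in A+T+, and CSF biomarker
# values drawn on the correct side of the A/T cutoffs.

suppressPackageStartupMessages(library(morphocov))

seed <- 20240901L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
cohort <- generate_cohort(cfg)
parc <- generate_sphere_parcellation(n_parcels = 100, n_networks = 7,
                                     seed = seed + 1L)

utils::write.csv(cohort, "results/cohort.csv", row.names = FALSE)
utils::write.table(parc, "results/parcellation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("sessions:", nrow(cohort),
    " subjects:", length(unique(cohort$subject_id)),
    " parcels:", nrow(parc), "\n")
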