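#!/usr/bin/env Rscript
# Stage 4: cluster separability of the biomarker groups in a 2-D embedding
# of the ICV-adjusted volumes (SGCC), overall and stratified by sex.

suppressPackageStartupMessages(library(morphocov))

prepped <- tibble::as_tibble(
  utils::read.csv("results/cohort_prepped.csv", check.names = FALSE))
vols <- volume_matrix(prepped)

overall <- sgcc_by_stratum(vols, prepped$at_group, method = "pca2d")
by_sex <- sgcc_by_stratum(vols, prepped$at_group, strata = prepped$sex,
                          method = "pca2d")
out <- dplyr::bind_rows(
  dplyr::mutate(overall, stratum = "all"),
  by_sex)
utils::write.table(out, "results/sgcc.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
print(as.data.frame(out), digits = 3)
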