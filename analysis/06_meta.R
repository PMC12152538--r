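#!/usr/bin/env Rscript
# Stage 6: random-effects (REML) meta-analysis across the discovery cohort
# and three independently generated validation cohorts, pooling per-region
# log-odds for each contrast, with BH correction across pooled regions.

suppressPackageStartupMessages(library(morphocov))

seed <- 20240906L
prepped <- tibble::as_tibble(
  utils::read.csv("results/cohort_prepped.csv", check.names = FALSE))

contrasts <- list(
  amyloid = c("A_T_MINUS", "CONTROL"),
  tau_given_amyloid = c("A_T_PLUS", "A_T_MINUS"))

validation <- lapply(1:3, function(i) {
  prepare_cohort(generate_cohort(generator_config(seed = seed + i)))
})

for (nm in names(contrasts)) {
  studies <- c(
    list(discovery = per_region_association(prepped, contrasts[[nm]])),
    setNames(lapply(validation, per_region_association,
                    contrast = contrasts[[nm]]),
             paste0("validation", 1:3)))
  pooled <- pool_regions(studies)
  utils::write.table(pooled, sprintf("results/meta_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(nm, ": ", nrow(pooled), " pooled region(s), ",
      sum(pooled$p_fdr < 0.05), " significant after FDR\n", sep = "")
  if (nrow(pooled) > 0) {
    print(as.data.frame(pooled[order(pooled$p_fdr), ][
      1:min(5, nrow(pooled)), ]), digits = 3)
  }
}
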