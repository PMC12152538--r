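#!/usr/bin/env Rscript
# Stage 5: per-region logistic associations (adjusted for age and sex) for
# the amyloid contrast (A+T- vs control) and the tau-given-amyloid
# contrast (A+T+ vs A+T-), then a ridge classifier on the selected
# regions with cross-validated penalty choice and held-out AUROC.

suppressPackageStartupMessages(library(morphocov))

seed <- 20240905L
prepped <- tibble::as_tibble(
  utils::read.csv("results/cohort_prepped.csv", check.names = FALSE))

contrasts <- list(
  amyloid = c("A_T_MINUS", "CONTROL"),
  tau_given_amyloid = c("A_T_PLUS", "A_T_MINUS"))

for (nm in names(contrasts)) {
  assoc <- per_region_association(prepped, contrasts[[nm]])
  utils::write.table(assoc, sprintf("results/assoc_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- assoc$region[assoc$selected]
  cat(nm, ": ", sum(assoc$selected), " selected region(s): ",
      paste(sel, collapse = ", "), "\n", sep = "")
  if (length(sel) < 2) next
  report <- train_and_evaluate(prepped, sel, contrasts[[nm]],
                               classifier = "ridge",
                               cvconfig = cv_config(seed = seed))
  cat(sprintf("  ridge lambda=%.3f  AUROC=%.3f [%.3f, %.3f]  sens=%.2f  spec=%.2f\n",
              report$lambda, report$auroc, report$auroc_ci["low"],
              report$auroc_ci["high"], report$sensitivity,
              report$specificity))
  imp <- tibble::tibble(region = names(report$feature_importance),
                        importance = report$feature_importance)
  utils::write.table(imp, sprintf("results/importance_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
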