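#!/usr/bin/env Rscript
# Stage 7: spatial correspondence of the meta-analytically significant
# regions with the parcellation's networks, assessed by Dice overlap
# against a spin-test (random rotation) spatial null.

suppressPackageStartupMessages(library(morphocov))

seed <- 20240907L
parc <- tibble::as_tibble(
  utils::read.delim("results/parcellation.tsv", check.names = FALSE))

regions <- default_region_names()
owner <- assign_parcels_to_regions(parc, regions, seed = seed)

for (nm in c("amyloid", "tau_given_amyloid")) {
  path <- sprintf("results/meta_%s.tsv", nm)
  if (!file.exists(path)) next
  pooled <- utils::read.delim(path, check.names = FALSE)
  sig <- pooled$region[pooled$p_fdr < 0.05]
  if (length(sig) == 0) {
    cat(nm, ": no significant regions; spin test skipped\n", sep = "")
    next
  }
  res <- spin_null(owner %in% sig, parc, n_perm = 1000, seed = seed + 1L)
  utils::write.table(res, sprintf("results/spin_%s.tsv", nm), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat(nm, " (", length(sig), " significant regions):\n", sep = "")
  print(as.data.frame(res), digits = 3)
}
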