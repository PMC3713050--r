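#!/usr/bin/env Rscript
# Stage 1: simulate the two synthetic cohorts (n = 602 each) whose per-type
# parameters are the published baseline and follow-up summaries of the
# taxonomic ("ms", sizes 188/217/85/112) and Gaussian-mixture ("em",
# 188/159/136/119) classifications. Ground-truth type labels are kept so the
# downstream stages can be scored against the generator.

library(strokeTaxa)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
dir.create("results", showWarnings = FALSE)

for (preset in c("ms", "em")) {
  cohort <- generate_cohort(cohort_preset(preset, seed = seed))
  path <- file.path("results", paste0("cohort_", preset, ".csv"))
  write_cohort(cohort, path)
  cat(sprintf("preset '%s' (seed %d): %d patients, %d DM-positive -> %s\n",
              preset, seed, nrow(cohort), sum(cohort$dm), path))
  print(cbind(n = table(cohort$true_type),
              age = round(tapply(cohort$age, cohort$true_type, mean), 1),
              nihss = round(tapply(cohort$nihss, cohort$true_type, mean), 1)))
}
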