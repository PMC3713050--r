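#!/usr/bin/env Rscript
# Stage 5: clinical characterization of the taxonomic types. Follow-up
# Barthel/Rankin outcome grids, disability levels, the best-prognosis share,
# the published-summary ANOVA recomputation, and the rounded age/NIHSS gaps.

library(strokeTaxa)

cohort <- read_cohort("results/cohort_ms.csv")
labels <- utils::read.csv("results/ms_labels.csv")
stopifnot(identical(cohort$patient_id, labels$patient_id))
labels <- labels$ms_type

fu <- followup_summary(cohort, labels)
utils::write.table(fu, "results/followup_ms.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
dis <- disability_level(fu)
share <- best_prognosis_share(table(labels), dis)
cat("disability levels:", paste(names(dis), dis, sep = "=", collapse = " "), "\n")
cat(sprintf("best-prognosis share: %.1f%% of %d patients\n", share, length(labels)))

# rough-typing combinatorics: 3 age bands x 3 NIHSS bands x 2 DM statuses
cat("possible rough types:", count_combinations(c(3, 3, 2)), "\n")

# age/NIHSS gaps between types, on this cohort's realized means
age_s <- group_summary(cohort$age, labels)
nihss_s <- group_summary(cohort$nihss, labels)
cat("age gap (type with highest vs lowest mean, rounded to years):",
    gap_arithmetic(max(age_s$mean), min(age_s$mean), "integer"), "\n")
cat("NIHSS gap (highest vs lowest mean, one decimal):",
    gap_arithmetic(max(nihss_s$mean), min(nihss_s$mean), "one_decimal"), "\n")

# published-summary ANOVA recomputation (printed n/mean/SD rows)
f_age <- anova_from_summaries(c(188, 159, 136, 119),
                              c(68.7, 76.9, 57.0, 67.6),
                              c(10.7, 6.7, 5.3, 16.6))
cat(sprintf("ANOVA from printed summaries (age row): F = %.1f\n", f_age$F))
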