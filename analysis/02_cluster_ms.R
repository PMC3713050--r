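#!/usr/bin/env Rscript
# Stage 2: the taxonomic arm. Normalize age/NIHSS/DM into 0-1, compute the
# Marczewski-Steinhaus (Soergel) distance matrix, build the complete-linkage
# dendrogram and cut it into four types. Writes the distance matrix,
# dendrogram (Newick), labels, per-type summaries with one-way ANOVA, and the
# rough categorical typing.

library(strokeTaxa)

cohort <- read_cohort("results/cohort_ms.csv")
fit <- ms_pipeline(cohort, k = 4, mode = "soergel")

utils::write.table(round(unclass(fit$distances), 6), "results/ms_distances.tsv",
                   sep = "\t", quote = FALSE, col.names = NA)
writeLines(to_newick(fit$tree), "results/ms_dendrogram.nwk")
utils::write.csv(data.frame(patient_id = names(fit$labels),
                            ms_type = as.integer(fit$labels)),
                 "results/ms_labels.csv", row.names = FALSE, quote = FALSE)

cat("type sizes:", as.integer(table(fit$labels)), "\n")
for (v in c("age", "nihss")) {
  gs <- group_summary(cohort[[v]], fit$labels)
  an <- anova_oneway_raw(cohort[[v]], fit$labels)
  cat(sprintf("%s means: %s | F(%d, %d) = %.1f, p = %.2g\n", v,
              paste(round(gs$mean, 1), collapse = "/"),
              an$df_between, an$df_within, an$F, an$p))
}
age_s <- group_summary(cohort$age, fit$labels)
nihss_s <- group_summary(cohort$nihss, fit$labels)
dm_modal <- as.vector(tapply(cohort$dm, fit$labels, function(x) mean(x) >= 0.5))
rough <- cbind(type = age_s$label,
               rough_categorize(age_s$mean, nihss_s$mean, dm_modal))
utils::write.table(rough, "results/ms_rough_types.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(rough)
if ("true_type" %in% names(cohort))
  cat("adjusted Rand index vs ground truth:",
      round(adjusted_rand_index(fit$labels, cohort$true_type), 3), "\n")
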