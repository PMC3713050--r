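#!/usr/bin/env Rscript
# Stage 4: concordance of the two arms. Optimal (Hungarian) alignment of the
# arbitrary cluster numberings, then direct agreement and Cohen's kappa with
# large-sample inference.

library(strokeTaxa)

ms <- utils::read.csv("results/ms_labels.csv")
em <- utils::read.csv("results/em_labels.csv")
stopifnot(identical(ms$patient_id, em$patient_id))

rep <- agreement_report(ms$ms_type, em$em_type)
print(rep)
print(rep$confusion)
strokeTaxa:::.write_json(
  list(confusion = unname(as.matrix(rep$confusion)), matching = rep$matching,
       direct_agreement = rep$direct_agreement, kappa = rep$kappa,
       kappa_se = rep$kappa_se, z = rep$z, p = rep$p),
  "results/agreement.json")
cat("wrote results/agreement.json\n")
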