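# strokeTaxa

Unsupervised phenotyping of ischemic-stroke cohorts from three admission
features — age, NIHSS score, and diabetes mellitus (DM) status — by two
deliberately different routes, and quantification of how well they agree:

1. **Taxonomic (M-S) arm.** Features are min-max normalized into [0, 1];
   patient dissimilarity is the Marczewski–Steinhaus distance, whose scalar
   form is `D(a, b) = |a − b| / max(a, b)` and whose vector form is the
   Soergel metric `D(u, v) = Σᵢ|uᵢ − vᵢ| / Σᵢ max(uᵢ, vᵢ)`; a
   complete-linkage dendrogram over the distance matrix is cut into *k*
   patient types (default *k* = 4).
2. **Mixture (E-M) arm.** A *G*-component Gaussian mixture is fitted to the
   raw-scale features by a from-scratch expectation–maximization algorithm
   (log-space E step, ridge-regularized M step, farthest-point restarts),
   and patients are MAP-classified.

Agreement between the two partitions is measured after optimal (Hungarian)
alignment of the arbitrary cluster numberings: direct agreement percentage
and Cohen's κ = (pₒ − pₑ)/(1 − pₑ) with large-sample inference. The
resulting types are characterized clinically: per-type baseline summaries
with one-way ANOVA (from raw data, or recomputed from published n/mean/SD
rows alone), rough categorical typing (age younger/medium/older, NIHSS
lower/medium/higher, DM ±), follow-up disability outcomes on the Barthel
Index (BI, 0–100) and modified Rankin Scale (mRS, 0–6) at days
30/90/180/360, and the share of patients with favorable prognosis.

Because no patient-level data is distributed, the package ships a
synthetic-cohort generator: four latent patient types with truncated-normal
age/NIHSS, deterministic DM status, and follow-up outcomes coupled through a
latent severity factor (BI loads negatively, mRS positively), with
ground-truth labels so the whole pipeline is testable end to end. Two
presets ("ms", "em") carry the published per-type summaries of a 602-patient
stroke cohort.

Intended users: biostatisticians and clinical epidemiologists exploring
cluster structure in small clinical feature sets, and anyone wanting a
transparent, fully tested reference for the Soergel/M-S taxonomy versus
Gaussian-mixture comparison.

## Worked example

```r
library(strokeTaxa)

cohort <- generate_cohort(cohort_preset("ms", seed = 1))   # 602 patients
ms <- ms_pipeline(cohort, k = 4)       # normalize -> Soergel -> complete linkage
em <- em_pipeline(cohort, gmm_config(G = 4, seed = 1001))  # EM mixture
agreement_report(ms$labels, em$labels)
#> direct agreement 90.2%, kappa = 0.865 (z = 36, p = 4.07e-283)

table(ms$labels)                       # type sizes, numbered by size
#>   1   2   3   4
#> 188 182 132 100
tapply(cohort$dm, ms$labels, mean)     # type 1 is the all-DM-positive type
#>   1   2   3   4
#>   1   0   0   0

anova_from_summaries(ns = c(188, 159, 136, 119),
                     means = c(68.7, 76.9, 57.0, 67.6),
                     sds = c(10.7, 6.7, 5.3, 16.6))
#> F(3, 598) = 89.69, p = 6.22e-48
```

The taxonomic cut isolates the DM-positive type exactly (all 188 DM-positive
patients and nobody else), the two arms agree substantially (κ well above
0.6), and the summary-level ANOVA reproduces a published F row from its
printed n/mean/SD alone.

The same analysis, stage by stage with all intermediate artifacts written
under `results/`, is scripted in `analysis/01_simulate.R` through
`analysis/05_characterize.R` (run them in order from the repository root;
each takes an optional seed argument).

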