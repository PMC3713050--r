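Package: strokeTaxa
Title: Taxonomic Clustering of Ischemic-Stroke Phenotypes and a Gaussian-Mixture Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotype taxonomy in ischemic-stroke cohorts: a
    synthetic-cohort generator with four latent patient types (age, NIHSS,
    diabetes status, and Barthel/Rankin follow-up), the Marczewski-Steinhaus
    (Soergel) distance with complete-linkage hierarchical clustering, a
    from-scratch expectation-maximization fitter for Gaussian mixtures,
    agreement statistics between partitions (optimal label matching, direct
    agreement, Cohen's kappa), and cluster characterization utilities
    including one-way ANOVA recomputed from published n/mean/SD summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
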