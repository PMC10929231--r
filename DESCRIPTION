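Package: resiliome
Title: Perturbation and Resilience Analysis of Longitudinal Multi-Omic Gut Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies antibiotic-induced perturbation and subsequent
    resilience of the gut microbiome from longitudinal multi-omic cohorts.
    Computes per-sample derived metrics (metagenomic-species abundances with a
    marker-gene detection rule, observed richness, rarefaction,
    beta-lactamasome relative abundance, cholesterol conversion and bile-acid
    transformation ratios, fungal load), turns them into per-subject
    trajectories (distances from baseline with 1 - s^2 structure distances,
    pre-treatment normalisation with a cohort-median fallback,
    delay-standardised trapezoidal AUCs, maximal perturbation and maximal
    resilience), and provides the statistical layer (random-intercept variance
    components and coefficients of variation, Wilcoxon tests against reference
    values, Spearman correlograms, Benjamini-Hochberg correction). A seeded
    synthetic cohort generator emulates a 22-subject two-arm twelve-timepoint
    design so the whole pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
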