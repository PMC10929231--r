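# resiliome

Quantifying perturbation and resilience of the gut microbiome in
longitudinal multi-omic cohorts.

## The problem

Short courses of intravenous β-lactam antibiotics disturb many components
of the gut ecosystem at once: the bacterial and phage communities, the
fungal microbiota, the faecal metabolome, the repertoire of antibiotic
resistance genes (the resistome, and within it the β-lactamasome), and
microbial metabolic functions such as cholesterol conversion to
coprostanol and primary-to-secondary bile-acid transformation. Comparing
*how far* each component departs from its pre-treatment state, and *how
closely* it returns weeks later, requires putting very different kinds of
measurements on one common scale. `resiliome` implements that framework
for cohorts sampled repeatedly around a treatment window (here: days −15,
−7, −1, 1, 2, 3, 4, 7, 10, 15, 30, 90 relative to treatment start), for
statisticians and microbiome researchers analysing such trials.

## The method

Variables are classified as **high-dimensional** (feature-abundance
structures: bacterial species, phage contigs, fungal OTUs, metabolite
features) or **low-dimensional** (scalar counts, richness values,
activities and ratios; all but richness analysed on the log10 scale).
For each subject a baseline sample is chosen (day −1, else −7, else −15)
and a **raw distance from baseline** is computed at every sampling time:

- high-dimensional: `1 − s²`, where `s` is Spearman's rank correlation of
  the structure between that day and baseline, over features present in at
  least one of the two profiles;
- low-dimensional: the absolute change from baseline on the analysis
  scale.

Raw distances are **normalised** by each subject's mean pre-treatment
distance (days −7/−15; cohort-median fallback when both are missing), so
a value of 1 means "as different from baseline as the subject's normal
week-to-week variation". Time courses are condensed into
delay-standardised trapezoidal AUCs over the actual collection times
(`AUC_D0–D10`, `AUC_D0–D30`, rescaled by `window / T` so a null
trajectory integrates exactly to its reference), the **maximal
perturbation** (largest normalised distance up to day 10) and the
**maximal resilience** (smallest normalised distance on days 15/30/90).
The statistical layer provides random-intercept variance components with
between/within-subject CVs, one-sample Wilcoxon tests of each metric
against its null reference (0 for changes, 1/10/30 for normalised
distances and their AUCs), Spearman correlograms across the 17-metric
panel (136 unordered pairs), and global Benjamini–Hochberg correction as
a sensitivity analysis.

A seeded synthetic-cohort generator (22 subjects, two arms, 12
timepoints, antibiotic-induced depletion with recovery, random
missingness) makes the whole pipeline runnable and testable at desk
scale.

## Worked example

The numbered scripts under `analysis/` run the full study narrative:

```sh
Rscript analysis/01_simulate.R                 # cohort -> results/cohort/
Rscript analysis/02_sample_metrics.R           # derived per-sample metrics
Rscript analysis/03_perturbation_resilience.R  # the core analysis
```

`01_simulate.R` prints

```
cohort: 22 subjects, 250 samples retained of 264 scheduled
scalar variables: 13; community layers: 4; ARD genes: 200
```

(264 = 22 × 12 scheduled samples; 5% are randomly missing).
`02_sample_metrics.R` shows the treatment effect in the derived metrics:

```
bacterial rarefied richness, median: day -1 91 -> day 4 84
beta-lactamasome proportion, median: day -1 0.087 -> day 4 0.377
```

i.e. bacterial richness falls while β-lactamase genes are enriched among
surviving resistance determinants. `03_perturbation_resilience.R` prints
the pre-treatment variability table (between-subject CVs of 2.4% for
bacterial counts up to ~135% for cholesterol conversion, matching the
scales the generator emulates), then

```
Wilcoxon battery: 65 of 119 metric tests significant at 0.05 (65 after BH)
variables perturbed at day 4: bacteria_MGS, bacterial_counts, ...
correlogram [perturbation]: 136 tests; significant at alpha = 0.05: 6 (4.4%); after BH: 0 (0.0%)
```

Most variables are detectably perturbed at day 4, while pairwise
correlations between the *degrees* of perturbation of different
components are few and mostly do not survive false-discovery correction —
the generator simulates components independently, so this is the expected
behaviour and illustrates what the correlograms measure. All tables land
under `results/report/`, including `run_log.tsv` with every exclusion and
fallback decision.

In R, the same pipeline is one call:

```r
library(resiliome)
cohort <- simulate_cohort(n_subjects = 22, seed = 1)
res <- run_pipeline(cohort, "results/report")
res$correlograms$perturbation
#> correlogram [perturbation]: 136 tests; ...
```

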