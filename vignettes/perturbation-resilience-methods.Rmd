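---
title: "Quantifying gut-microbiome perturbation and resilience: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut-microbiome perturbation and resilience: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resiliome)
```

## The analytical model

`resiliome` treats a longitudinal multi-omic trial as a collection of
per-subject trajectories, one per variable, each referenced to that
subject's own pre-treatment state. The central quantity is a *normalised
distance from baseline*:

\[
D_{ivt} \;=\; \frac{d_{ivt}}{\bar d_{iv}^{\,\text{pre}}},
\]

where \(d_{ivt}\) is the raw distance of subject \(i\), variable \(v\) at
time \(t\), and \(\bar d_{iv}^{\,\text{pre}}\) is the mean raw distance of
the same subject over the pre-treatment days that are not the baseline day.
\(D = 1\) therefore means "as far from baseline as this subject drifts on
an ordinary week", which is what makes bacterial counts, metabolome
structures and enzymatic activities comparable on one axis.

Raw distances differ by dimensionality:

* **high-dimensional structures** (bacterial species, phage contigs,
  fungal OTUs, metabolite features): \(d = 1 - s^2\), with \(s\) the
  Spearman correlation between the profile at \(t\) and the baseline
  profile. Using \(s^2\) makes the distance direction-agnostic (a perfect
  anti-correlation is still a perfectly predictable structure) and bounds
  it in \([0, 1]\);
* **low-dimensional scalars**: the absolute change from baseline on the
  analysis scale. All scalars except richness counts are log10-transformed
  first, so changes are fold-changes; richness stays on the natural scale
  because a difference in detected features is already the meaningful
  unit.

The assumptions are modest but worth stating: within-subject pre-treatment
variation is a meaningful yardstick (at least two pre-treatment samples
per subject, or a cohort of comparable subjects for the fallback);
monotone relationships are what matters in structure comparisons (ranks,
not magnitudes); and samples are independent given the subject.

### Baseline and normalisation rules

The baseline sample is day −1, else day −7, else day −15; a subject with
no pre-treatment sample is excluded (and logged). The normaliser uses the
pre-treatment days *other than* the chosen baseline: including the
baseline's own distance (identically 0) would halve every divisor and
build a bias into \(D\). When neither day −7 nor −15 is available the
divisor falls back to the cohort median of the other subjects' divisors
for that variable; when the divisor is exactly 0 (a subject whose
pre-treatment samples are identical) the normalised series is reported
missing rather than infinite — the downstream statistics are rank-based
and tolerate missingness pairwise. Every one of these decisions is
recorded in the run log with a machine-readable code.

### Time-course condensation

Trajectories are condensed into four per-subject numbers:

* `AUC_D0_D10` and `AUC_D0_D30`: trapezoidal integrals over the *actual*
  collection times, anchored at \(t = 0\) with the null value (0 for
  signed changes, 1 for normalised distances), ending at the actual time
  \(T\) of the last sample with nominal day inside the window, and
  rescaled by \(\text{window}/T\). This delay-standardisation is the only
  reading under which a null trajectory integrates exactly to its
  reference (0, 10 or 30) regardless of each subject's collection delays,
  which is what the one-sample Wilcoxon tests compare against. When the
  day-10/day-30 sample is missing, the window ends at the latest earlier
  sample and the substitution is logged.
* `max_perturbation`: the largest normalised distance at nominal days 1–10.
* `max_resilience`: the smallest normalised distance at days 15/30/90
  (smaller = closer return to baseline).

Low-dimensional AUCs use the *signed* change (tested against 0) while
maximal perturbation/resilience use normalised absolute distances; the
two conventions serve different questions (directional net effect vs
magnitude of displacement) and are deliberately not merged.

## Statistical layer

* **Variance components**: the random-intercept model
  \(y_{ij} = \mu + b_i + e_{ij}\) is fitted by REML via `lme4::lmer` to
  the pre-treatment samples, reporting between/within-subject SDs and CVs
  (\(100 \cdot \text{SD}/|\mu|\), on the analysis scale — the absolute
  value keeps CVs positive for log-scale variables with negative means).
  The degenerate case of zero residual variance is computed directly
  (within-SD 0, between-SD = SD of subject means) instead of pushing a
  boundary problem into the optimiser. On balanced designs the REML fit
  coincides with the closed-form one-way ANOVA estimator; the test suite
  verifies this to 10⁻⁶.
* **Wilcoxon tests**: one-sample signed-rank against the null reference,
  two-sided, zeros dropped before ranking, exact null for ≤ 25 untied
  differences, normal approximation with continuity correction otherwise;
  a two-group rank-sum variant compares treatment arms.
* **Spearman tests**: mid-rank \(\rho\) with pairwise-complete missing
  handling; exact permutation p for ≤ 9 pairs, otherwise the
  t-approximation \(t = \rho\sqrt{(n-2)/(1-\rho^2)}\).
* **Correlograms**: all \(\binom{17}{2} = 136\) unordered pairs of the
  default panel for the perturbation and resilience modes, and the
  13 × 17 rectangular grid of untransformed baseline values against
  outcomes for the baseline modes. Benjamini–Hochberg correction is
  applied once per mode (globally), as a sensitivity analysis at
  \(\alpha = 0.05\) two-sided.

## The synthetic cohort generator

The generator's defaults encode the study conditions the analysis is
designed for: 22 subjects randomised 1:1 to two arms, the 12-day schedule
(−15 … 90), collection times jittered uniformly on ±0.25 day (small
enough to keep nominal-day labels unambiguous), and 5% random sample
missingness with at least one pre-treatment sample forced present per
subject.

* **Scalars** follow
  \(y = \mu + b_i + \delta(t) + e\) on the analysis scale, with
  \(b_i \sim N(0, \sigma_b^2)\), \(e \sim N(0, \sigma_w^2)\) and a
  gamma-pulse deflection
  \(\delta(t) = -A\,(t/p)\,e^{1-t/p}\, 2^{-\max(0,\,t-p)/h}\)
  (peak day \(p\), recovery half-life \(h\)); log10 variables are
  reported as \(10^y\). The 13 default variables use baseline means and
  between/within SDs on the scales typical of healthy-volunteer cohorts
  (e.g. bacterial counts: mean 11.3 log10 CFU/g, between-SD 0.19,
  within-SD 0.14), with amplitudes chosen once to reproduce the
  qualitative post-antibiotic pattern (marked richness loss, transient
  Enterobacterales crash, β-lactamase enrichment, fungal-load increase,
  no fungal-community effect). The between-subject SD of metabolome
  richness is set to a plausible ~4% CV rather than the near-zero value a
  boundary REML fit can produce on real data.
* **Communities** draw a per-subject Dirichlet baseline composition
  (concentration 0.3 for the uneven bacterial layer), multiply a fixed
  `kill_fraction` subset of features by `kill_depth` while antibiotic
  pressure lasts (through day 4) with an exponential return
  (half-life `recovery_halflife`), renormalise, and emit multinomial
  counts at `sequencing_depth`. The pulse shape is a design choice — any
  smooth, monotone-post-peak depletion/recovery curve would serve — and
  was chosen as the minimal such curve.
* **The resistome** assigns genes to the five Ambler β-lactamase families
  (in catalogue proportions) and `otherARD`, with complementary
  depletion/enrichment pulses so that the β-lactamasome proportion rises
  transiently after treatment.

What the generator does *not* emulate: inter-variable correlation
(components are simulated independently unless the user builds them
coupled), phage–bacteria dynamics, pharmacokinetics of faecal antibiotic
concentrations, compositional read-level artefacts, or arm differences
(the two arms carry no effect difference by default, matching the absence
of detectable differences between the two cephalosporins). Passing tests
therefore demonstrate the *pipeline's* correctness and calibration, not
biological claims about real cohorts — in particular, real correlograms
may show genuine cross-component correlations that the independent
generator cannot produce.

One emergent property worth knowing: observed richness of a multinomial
sample responds to depletion only when sequencing depth is shallow
relative to community evenness — a 100-fold depletion of a feature that
still exceeds the detection threshold does not remove it. The richness
property tests therefore run at depth 500 on an uneven 50-feature
community, while structure distances (rank-based) detect the same
depletion at any depth.

## Numerical choices and degenerate inputs

* Spearman support for structure distances: features non-zero in at least
  one of the two profiles; shared absences carry no rank information and
  would inflate \(s\). Ties take mid-ranks. Supports of fewer than 3
  features, or zero rank variance, yield missing distances.
* The 10% marker-detection rule in `mgs_abundance` counts a marker as
  "seen" when its count is strictly positive; marker sets of any size are
  allowed (the rule applies fractionally). Profiles renormalise to sum
  to 1 within 10⁻⁹; an all-zero profile stays all-zero.
* `rarefy_counts` draws without replacement (multivariate
  hypergeometric, exhaustive-urn sampling); a requested depth above the
  sample total is an error, mirroring the convention of choosing the
  rarefaction threshold to include all samples.
* β-lactamasome abundance with zero total ARD copies is missing, not 0.
* Ratio metrics (`cholesterol_conversion_rate`,
  `bile_acid_transformation`, `fungal_load`) are scale-invariant and
  return missing on empty denominators; the fungal-load DNA threshold
  (default 50, in the assay's concentration units) excludes low-yield
  samples.
* All significance is two-sided at \(\alpha = 0.05\); BH-adjusted values
  are reported alongside raw ones, never instead of them.

## Problem sizes

The test-suite simulations use the cohort sizes the framework targets:
22 subjects for calibration checks (200 replicate null cohorts for the
type-I error of the AUC Wilcoxon tests, checked against a binomial 99%
envelope), 200 subjects × 3 pre-treatment samples for variance-component
recovery (within 15% relative error), and 10⁴ replicates for the
hypergeometric rarefaction checks. `scripts/acceptance.R` recomputes the
same quantities from scratch under a user-supplied seed.

## Known limitations

* The 1 − s² distance is insensitive to proportional changes that
  preserve ranks; a community uniformly scaled up is "unperturbed", which
  is intended (structure, not load) but means total-load effects must be
  carried by the scalar panel.
* Variance components assume a single random intercept; day-level or
  arm-level random effects are out of scope.
* The exact Spearman permutation null is enumerated only to n = 9
  (9! ≈ 3.6 × 10⁵ permutations); beyond that the t-approximation is used,
  which is standard but approximate in the tails.
* No imputation: windows with missing terminal samples shrink (and are
  logged) rather than being extrapolated.
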