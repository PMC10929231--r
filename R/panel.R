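#' Default nominal sampling schedule
#'
#' Twelve nominal collection days relative to the start of antibiotic
#' treatment (day 0): three pre-treatment days (-15, -7, -1), daily sampling
#' during and just after the 3-day course (1-4), and follow-up out to day 90.
#'
#' @return Integer vector of nominal days, strictly increasing.
#' @export
default_schedule <- function() {
  c(-15L, -7L, -1L, 1L, 2L, 3L, 4L, 7L, 10L, 15L, 30L, 90L)
}

#' Specification of one low-dimensional (scalar) variable
#'
#' Describes a scalar per-sample variable on its analysis scale: the scale on
#' which distances and variance components are computed. Variables with
#' `transform = "log10"` are simulated and analysed as log10 values but
#' reported (and stored in cohort tables) on the natural scale; richness-type
#' variables use `transform = "identity"`.
#'
#' @param name Variable name.
#' @param transform `"log10"` or `"identity"`.
#' @param baseline_mean Mean at baseline, on the analysis scale.
#' @param between_sd,within_sd Between-subject and within-subject standard
#'   deviations on the analysis scale; both must be non-negative.
#' @param perturbation_amplitude Peak deflection on the analysis scale. A
#'   positive amplitude depletes the variable after treatment; a negative one
#'   increases it. Zero means no treatment effect.
#' @param peak_day Day of maximal deflection (default 4, the day after the
#'   end of a 3-day course).
#' @param recovery_halflife Half-life (days) of the post-peak exponential
#'   return towards baseline; must be positive.
#' @return An object of class `scalar_spec`.
#' @export
scalar_spec <- function(name, transform = c("log10", "identity"),
                        baseline_mean, between_sd, within_sd,
                        perturbation_amplitude = 0, peak_day = 4,
                        recovery_halflife = 10) {
  transform <- match.arg(transform)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (between_sd < 0 || within_sd < 0)
    stop("between_sd and within_sd must be >= 0")
  if (recovery_halflife <= 0)
    stop("recovery_halflife must be > 0")
  structure(
    list(name = name, transform = transform,
         baseline_mean = baseline_mean,
         between_sd = between_sd, within_sd = within_sd,
         perturbation_amplitude = perturbation_amplitude,
         peak_day = peak_day, recovery_halflife = recovery_halflife),
    class = "scalar_spec"
  )
}

#' Specification of one high-dimensional community layer
#'
#' Parameters of the compositional generator for one omic layer: a Dirichlet
#' baseline community per subject, a multiplicative depletion of a fixed
#' subset of features while antibiotic pressure lasts, an exponential return
#' of the depleted features after the end of treatment, and multinomial
#' count sampling at a fixed sequencing depth.
#'
#' @param layer Layer label (e.g. `"bacteria_MGS"`).
#' @param n_features Number of features; at least 3.
#' @param baseline_concentration Dirichlet concentration of the baseline
#'   community (smaller = more uneven).
#' @param kill_fraction Fraction of features depleted by treatment, in
#'   \[0, 1\].
#' @param kill_depth Multiplicative depletion factor at full effect, in
#'   (0, 1\].
#' @param recovery_halflife Half-life (days) of the return of depleted
#'   features after day 4.
#' @param sequencing_depth Total counts drawn per sample.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(layer, n_features = 100,
                           baseline_concentration = 0.3,
                           kill_fraction = 0.5, kill_depth = 0.01,
                           recovery_halflife = 10,
                           sequencing_depth = 1e5) {
  stopifnot(is.character(layer), length(layer) == 1L)
  if (n_features < 3) stop("n_features must be >= 3")
  if (kill_fraction < 0 || kill_fraction > 1)
    stop("kill_fraction must be in [0, 1]")
  if (kill_depth <= 0 || kill_depth > 1)
    stop("kill_depth must be in (0, 1]")
  if (recovery_halflife <= 0) stop("recovery_halflife must be > 0")
  if (sequencing_depth < 1) stop("sequencing_depth must be >= 1")
  structure(
    list(layer = layer, n_features = as.integer(n_features),
         baseline_concentration = baseline_concentration,
         kill_fraction = kill_fraction, kill_depth = kill_depth,
         recovery_halflife = recovery_halflife,
         sequencing_depth = as.integer(sequencing_depth)),
    class = "community_spec"
  )
}

#' Default variable panel
#'
#' The 17-metric panel used throughout: 13 low-dimensional scalar variables
#' (counts, richness, activities and metabolic ratios) and 4 high-dimensional
#' community structures (bacterial species, phage contigs, fungal OTUs,
#' metabolite features). Richness variables are analysed untransformed; all
#' other scalars are log10-transformed. Structures carry no transform.
#'
#' @return A data frame with columns `name`, `dimensionality`
#'   (`"low"`/`"high"`) and `transform` (`NA` for high-dimensional rows).
#' @export
default_panel <- function() {
  low <- vapply(default_scalar_specs(), function(s) s$name, character(1))
  tr <- vapply(default_scalar_specs(), function(s) s$transform, character(1))
  high <- vapply(default_community_specs(), function(s) s$layer, character(1))
  data.frame(
    name = c(low, high),
    dimensionality = c(rep("low", length(low)), rep("high", length(high))),
    transform = c(tr, rep(NA_character_, length(high))),
    stringsAsFactors = FALSE
  )
}

#' Default scalar variable specifications
#'
#' Baseline means and between/within-subject standard deviations are on the
#' analysis scale and follow the magnitudes typical of a healthy-volunteer
#' cohort (e.g. total bacterial counts around 10^11.3 CFU/g with a
#' between-subject SD of 0.19 log10 units). Perturbation amplitudes, peak
#' days and recovery half-lives encode the qualitative post-antibiotic
#' pattern: a marked drop in bacterial and phage richness, a deep transient
#' reduction of Enterobacterales, an increase in beta-lactamase gene
#' abundance and activity and in fungal load, no effect on the fungal
#' microbiome, and a transient loss of cholesterol-conversion and bile-acid
#' transformation capacity.
#'
#' @return Named list of [scalar_spec()] objects (13 variables).
#' @export
default_scalar_specs <- function() {
  specs <- list(
    scalar_spec("bacterial_counts", "log10", 11.3, 0.19, 0.14,
                perturbation_amplitude = 0.5, peak_day = 4,
                recovery_halflife = 5),
    scalar_spec("bacterial_richness", "identity", 269.7, 64.69, 16.0,
                perturbation_amplitude = 120, peak_day = 4,
                recovery_halflife = 10),
    scalar_spec("enterobacterales_counts", "log10", 7.5, 1.37, 1.00,
                perturbation_amplitude = 3.0, peak_day = 4,
                recovery_halflife = 5),
    scalar_spec("resistome_richness", "identity", 820.1, 159.50, 69.75,
                perturbation_amplitude = 250, peak_day = 4,
                recovery_halflife = 15),
    scalar_spec("betalactamasome_abundance", "log10", -0.8, 0.03, 0.02,
                perturbation_amplitude = -0.15, peak_day = 4,
                recovery_halflife = 5),
    scalar_spec("betalactamase_activity", "log10", 1.2, 0.59, 0.20,
                perturbation_amplitude = -0.8, peak_day = 4,
                recovery_halflife = 5),
    scalar_spec("phage_richness", "identity", 1226.6, 271.81, 91.37,
                perturbation_amplitude = 300, peak_day = 3,
                recovery_halflife = 3),
    scalar_spec("fungal_load", "log10", -5.2, 0.72, 1.27,
                perturbation_amplitude = -0.8, peak_day = 4,
                recovery_halflife = 10),
    scalar_spec("fungal_richness", "identity", 25.6, 4.77, 9.13,
                perturbation_amplitude = 0),
    scalar_spec("calbicans_dna", "log10", -5.0, 0.81, 0.47,
                perturbation_amplitude = 0),
    scalar_spec("metabolome_richness", "identity", 1472.7, 60, 98.85,
                perturbation_amplitude = 50, peak_day = 4,
                recovery_halflife = 10),
    scalar_spec("cholesterol_conversion", "log10", -0.6, 1.03, 0.49,
                perturbation_amplitude = 1.0, peak_day = 4,
                recovery_halflife = 3),
    scalar_spec("bile_acid_transformation", "log10", -0.1, 0.09, 0.06,
                perturbation_amplitude = 0.15, peak_day = 4,
                recovery_halflife = 3)
  )
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

#' Default community layer specifications
#'
#' Four omic layers with depletion/recovery dynamics matching the
#' qualitative cohort pattern: a profound depletion of half the bacterial
#' species recovering over weeks, a shallower and faster phage perturbation,
#' an unaffected fungal community, and a metabolome whose composition
#' recovers only slowly.
#'
#' @return Named list of [community_spec()] objects (4 layers).
#' @export
default_community_specs <- function() {
  specs <- list(
    community_spec("bacteria_MGS", n_features = 100,
                   baseline_concentration = 0.3, kill_fraction = 0.5,
                   kill_depth = 0.01, recovery_halflife = 10,
                   sequencing_depth = 1e5),
    community_spec("phage_contigs", n_features = 80,
                   baseline_concentration = 0.5, kill_fraction = 0.4,
                   kill_depth = 0.05, recovery_halflife = 4,
                   sequencing_depth = 5e4),
    community_spec("fungal_OTUs", n_features = 40,
                   baseline_concentration = 0.5, kill_fraction = 0,
                   kill_depth = 1, recovery_halflife = 5,
                   sequencing_depth = 2e4),
    community_spec("metabolites", n_features = 150,
                   baseline_concentration = 1.0, kill_fraction = 0.3,
                   kill_depth = 0.2, recovery_halflife = 30,
                   sequencing_depth = 1e5)
  )
  names(specs) <- vapply(specs, function(s) s$layer, character(1))
  specs
}
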