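#' @importFrom stats rnorm runif rgamma rmultinom rpois median
NULL

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 - 1 so it is a valid R integer seed.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stream) %% 2147483647)
}

# Gamma-pulse deflection with exponential post-peak recovery. Zero before
# treatment start; peaks at `peak_day`; halves every `recovery_halflife`
# days after the peak. A positive amplitude gives a negative deflection
# (depletion).
pulse_deflection <- function(t, amplitude, peak_day, recovery_halflife) {
  out <- numeric(length(t))
  post <- t > 0
  tp <- t[post]
  shape <- (tp / peak_day) * exp(1 - tp / peak_day)
  damp <- exp(-log(2) * pmax(0, tp - peak_day) / recovery_halflife)
  out[post] <- -amplitude * shape * damp
  out
}

#' Generate a longitudinal study design
#'
#' Builds a two-arm design with jittered actual collection times and random
#' sample missingness. Subjects are randomised 1:1 to the two arms. Each
#' sample's actual collection time is its nominal day plus a uniform jitter
#' on +/- 0.25 day. Each sample is dropped independently with probability
#' `missingness_rate`, except that at least one pre-treatment sample (day
#' -15, -7 or -1) is always retained per subject so that baseline selection
#' stays defined.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param schedule Nominal days, strictly increasing; see
#'   [default_schedule()].
#' @param missingness_rate Probability in \[0, 1) that any given sample is
#'   missing.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   design.
#' @param arms Two arm labels.
#' @return An object of class `study_design`: a list with `subjects`,
#'   `arms` (named character vector), `schedule`, `seed` and `samples`, a
#'   data frame with columns `sample_id`, `subject_id`, `arm`,
#'   `nominal_day`, `collection_time`.
#' @examples
#' d <- generate_design(4, seed = 1)
#' nrow(d$samples)  # 4 x 12 samples
#' @export
generate_design <- function(n_subjects = 22, schedule = default_schedule(),
                            missingness_rate = 0, seed = 1,
                            arms = c("ceftriaxone", "cefotaxime")) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(schedule) == 0) stop("schedule must be nonempty")
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must be in [0, 1)")
  stopifnot(length(arms) == 2L)

  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  arm_of <- sample(rep(arms, length.out = n_subjects))
  names(arm_of) <- subjects

  samples <- expand.grid(nominal_day = schedule, subject_id = subjects,
                         stringsAsFactors = FALSE)[, c(2, 1)]
  samples$arm <- arm_of[samples$subject_id]
  samples$collection_time <- samples$nominal_day +
    runif(nrow(samples), -0.25, 0.25)
  samples$sample_id <- sprintf("%s_D%d", samples$subject_id,
                               samples$nominal_day)

  if (missingness_rate > 0) {
    drop <- runif(nrow(samples)) < missingness_rate
    pre_days <- schedule[schedule < 0]
    for (s in subjects) {
      idx <- which(samples$subject_id == s &
                     samples$nominal_day %in% pre_days)
      if (length(idx) > 0 && all(drop[idx])) {
        # force the latest pre-treatment sample back in
        drop[idx[which.max(samples$nominal_day[idx])]] <- FALSE
      }
    }
    samples <- samples[!drop, , drop = FALSE]
  }
  samples <- samples[order(samples$subject_id, samples$nominal_day), ]
  rownames(samples) <- NULL
  samples <- samples[, c("sample_id", "subject_id", "arm", "nominal_day",
                         "collection_time")]

  structure(list(subjects = subjects, arms = arm_of,
                 schedule = as.integer(schedule), seed = seed,
                 samples = samples),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d subjects, %d nominal days, %d samples\n",
              length(x$subjects), length(x$schedule), nrow(x$samples)))
  invisible(x)
}

#' Simulate one scalar variable over a study design
#'
#' Values on the analysis scale are
#' `baseline_mean + b_subject + deflection(t) + e`, with subject intercepts
#' `b ~ N(0, between_sd^2)`, residuals `e ~ N(0, within_sd^2)` and a
#' gamma-pulse deflection with exponential recovery evaluated at the actual
#' collection time (zero before treatment). Variables with
#' `transform = "log10"` are reported on the natural scale (`10^value`).
#'
#' @param design A [generate_design()] object.
#' @param spec A [scalar_spec()].
#' @param seed Integer seed.
#' @return Data frame with one row per retained sample: `sample_id`,
#'   `subject_id`, `arm`, `nominal_day`, `collection_time`, `variable`,
#'   `value` (natural scale).
#' @export
simulate_scalar_series <- function(design, spec, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "scalar_spec"))
  set.seed(seed)
  b <- rnorm(length(design$subjects), 0, spec$between_sd)
  names(b) <- design$subjects
  s <- design$samples
  defl <- pulse_deflection(s$collection_time, spec$perturbation_amplitude,
                           spec$peak_day, spec$recovery_halflife)
  value <- spec$baseline_mean + b[s$subject_id] + defl +
    rnorm(nrow(s), 0, spec$within_sd)
  if (spec$transform == "log10") value <- 10^value
  data.frame(sample_id = s$sample_id, subject_id = s$subject_id,
             arm = s$arm, nominal_day = s$nominal_day,
             collection_time = s$collection_time,
             variable = spec$name, value = unname(value),
             stringsAsFactors = FALSE)
}

#' Simulate a community composition layer over a study design
#'
#' Each subject gets a Dirichlet baseline community, drawn once. For samples
#' after treatment start, a fixed subset of features (the first
#' `round(kill_fraction * n_features)` feature indices) is multiplied by a
#' depletion factor that equals `kill_depth` while antibiotic pressure lasts
#' (up to day 4) and then returns to 1 with half-life `recovery_halflife`;
#' the composition is renormalised and multinomial counts are drawn at
#' `sequencing_depth`.
#'
#' @param design A [generate_design()] object.
#' @param spec A [community_spec()].
#' @param seed Integer seed.
#' @return Data frame with one row per sample x feature: `sample_id`,
#'   `subject_id`, `nominal_day`, `collection_time`, `layer`, `feature_id`,
#'   `count`.
#' @export
simulate_composition_series <- function(design, spec, seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(spec, "community_spec"))
  set.seed(seed)
  nf <- spec$n_features
  features <- sprintf("%s_f%03d", spec$layer, seq_len(nf))
  n_kill <- round(spec$kill_fraction * nf)
  kill_idx <- seq_len(n_kill)

  base <- lapply(design$subjects, function(s) {
    g <- rgamma(nf, shape = spec$baseline_concentration)
    if (sum(g) == 0) g <- rep(1, nf)
    g / sum(g)
  })
  names(base) <- design$subjects

  s <- design$samples
  out <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    p <- base[[s$subject_id[i]]]
    t <- s$collection_time[i]
    if (t > 0 && n_kill > 0) {
      f <- spec$kill_depth * (1 + (1 / spec$kill_depth - 1) *
                                (1 - 2^(-max(0, t - 4) /
                                          spec$recovery_halflife)))
      p[kill_idx] <- p[kill_idx] * f
      p <- p / sum(p)
    }
    counts <- as.integer(rmultinom(1, spec$sequencing_depth, p))
    out[[i]] <- data.frame(sample_id = s$sample_id[i],
                           subject_id = s$subject_id[i],
                           nominal_day = s$nominal_day[i],
                           collection_time = s$collection_time[i],
                           layer = spec$layer, feature_id = features,
                           count = counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a resistome gene-count table over a study design
#'
#' Genes are assigned to the five beta-lactamase Ambler families (`blaA`,
#' `blaB1B2`, `blaB3`, `blaC`, `blaD`, in catalogue proportions) and to
#' `otherARD`. Per subject, each gene has a lognormal baseline abundance;
#' after treatment start non-beta-lactamase genes are depleted and
#' beta-lactamase genes enriched by complementary gamma pulses, so the
#' beta-lactamasome relative abundance rises transiently. Counts are
#' Poisson.
#'
#' @param design A [generate_design()] object.
#' @param n_genes Total number of ARD genes; at least 1.
#' @param bla_fraction Fraction of genes in beta-lactamase families, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param depletion Maximal fractional depletion of non-bla genes (default
#'   0.7).
#' @param enrichment Maximal fold-increase pulse of bla genes (default 1).
#' @return List with `genes` (data frame `sample_id`, `subject_id`,
#'   `nominal_day`, `gene_id`, `count`) and `annotation` (data frame
#'   `gene_id`, `family`).
#' @export
simulate_resistome <- function(design, n_genes = 200,
                               bla_fraction = 1823 / 19061, seed = 1,
                               depletion = 0.7, enrichment = 1) {
  stopifnot(inherits(design, "study_design"))
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (bla_fraction < 0 || bla_fraction > 1)
    stop("bla_fraction must be in [0, 1]")
  set.seed(seed)
  n_bla <- round(bla_fraction * n_genes)
  bla_families <- c("blaA", "blaB1B2", "blaB3", "blaC", "blaD")
  bla_weights <- c(627, 463, 463, 181, 89)
  fam <- c(
    if (n_bla > 0) rep(bla_families,
                       diff(round(cumsum(c(0, bla_weights / sum(bla_weights)))
                                  * n_bla))) else character(0),
    rep("otherARD", n_genes - n_bla)
  )
  annotation <- data.frame(gene_id = sprintf("ard_%04d", seq_len(n_genes)),
                           family = fam, stringsAsFactors = FALSE)
  is_bla <- fam != "otherARD"

  s <- design$samples
  out <- vector("list", nrow(s))
  lambda_by_subject <- lapply(design$subjects, function(x)
    exp(rnorm(n_genes, log(20), 0.8)))
  names(lambda_by_subject) <- design$subjects
  for (i in seq_len(nrow(s))) {
    lam <- lambda_by_subject[[s$subject_id[i]]]
    t <- s$collection_time[i]
    if (t > 0) {
      pulse <- -pulse_deflection(t, 1, 4, 10)  # in [0, 1], peak at day 4
      lam <- lam * ifelse(is_bla, 1 + enrichment * pulse,
                          1 - depletion * pulse)
    }
    out[[i]] <- data.frame(sample_id = s$sample_id[i],
                           subject_id = s$subject_id[i],
                           nominal_day = s$nominal_day[i],
                           gene_id = annotation$gene_id,
                           count = rpois(n_genes, lam),
                           stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, out), annotation = annotation)
}

#' Simulate a full multi-omic cohort
#'
#' Convenience wrapper: generates a design and simulates every scalar
#' variable of the panel, every community layer, and the resistome, with
#' per-stream child seeds derived from one master seed.
#'
#' @param n_subjects,schedule,missingness_rate,seed As in
#'   [generate_design()].
#' @param scalar_specs Named list of [scalar_spec()]s (default
#'   [default_scalar_specs()]).
#' @param community_specs Named list of [community_spec()]s (default
#'   [default_community_specs()]).
#' @param resistome Logical; also simulate the gene-count table.
#' @return A list of class `cohort`: `design`, `samples`, `scalars` (long
#'   data frame), `profiles` (long data frame), and optionally `genes` +
#'   `annotation`.
#' @export
simulate_cohort <- function(n_subjects = 22, schedule = default_schedule(),
                            missingness_rate = 0.05, seed = 1,
                            scalar_specs = default_scalar_specs(),
                            community_specs = default_community_specs(),
                            resistome = TRUE) {
  design <- generate_design(n_subjects, schedule, missingness_rate,
                            seed = child_seed(seed, 0))
  scalars <- do.call(rbind, lapply(seq_along(scalar_specs), function(i) {
    simulate_scalar_series(design, scalar_specs[[i]],
                           seed = child_seed(seed, i))
  }))
  profiles <- do.call(rbind, lapply(seq_along(community_specs), function(i) {
    simulate_composition_series(design, community_specs[[i]],
                                seed = child_seed(seed, 100 + i))
  }))
  out <- list(design = design, samples = design$samples,
              scalars = scalars[, c("sample_id", "variable", "value")],
              profiles = profiles[, c("sample_id", "layer", "feature_id",
                                      "count")])
  if (resistome) {
    res <- simulate_resistome(design, seed = child_seed(seed, 200))
    out$genes <- res$genes[, c("sample_id", "gene_id", "count")]
    out$annotation <- res$annotation
  }
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("cohort: %d subjects, %d samples, %d scalar variables,",
                     " %d layers\n"),
              length(x$design$subjects), nrow(x$samples),
              length(unique(x$scalars$variable)),
              length(unique(x$profiles$layer))))
  invisible(x)
}
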