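#' @importFrom utils read.delim write.table
NULL

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Write a cohort to TSV files
#'
#' Serialises a cohort as tab-separated UTF-8 tables with '.' decimals and
#' `NA` for missing values: `samples.tsv`, `scalars.tsv`, `profiles.tsv`
#' and, when present, `genes.tsv` + `gene_annotation.tsv`.
#'
#' @param cohort A `cohort` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_tsv(cohort$scalars, file.path(dir, "scalars.tsv"))
  write_tsv(cohort$profiles, file.path(dir, "profiles.tsv"))
  if (!is.null(cohort$genes)) {
    write_tsv(cohort$genes, file.path(dir, "genes.tsv"))
    write_tsv(cohort$annotation, file.path(dir, "gene_annotation.tsv"))
  }
  invisible(dir)
}

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: malformed header, missing column(s): %s", file,
                 paste(missing, collapse = ", ")))
}

#' Read a cohort from TSV files
#'
#' Reads and validates the tables written by [write_cohort()]. Duplicate
#' `(subject_id, nominal_day)` sample rows are a hard error naming the
#' offending rows; the literal string `NA` parses as a missing value; when
#' a `panel` is supplied, scalar variables and profile layers not in the
#' panel are rejected.
#'
#' @param dir Directory holding `samples.tsv`, `scalars.tsv`,
#'   `profiles.tsv` and optionally `genes.tsv` + `gene_annotation.tsv`.
#' @param panel Optional variable panel to validate against.
#' @return A `cohort` list.
#' @export
read_cohort <- function(dir, panel = NULL) {
  rd <- function(f) read.delim(file.path(dir, f), sep = "\t",
                               stringsAsFactors = FALSE)
  samples <- rd("samples.tsv")
  check_columns(samples, c("sample_id", "subject_id", "arm", "nominal_day",
                           "collection_time"), "samples.tsv")
  dup <- duplicated(samples[, c("subject_id", "nominal_day")])
  if (any(dup))
    stop(sprintf("samples.tsv: duplicated (subject, nominal_day) in row(s) %s",
                 paste(which(dup), collapse = ", ")))
  if (!is.numeric(samples$nominal_day) ||
      !is.numeric(samples$collection_time))
    stop("samples.tsv: nominal_day and collection_time must be numeric")

  scalars <- rd("scalars.tsv")
  check_columns(scalars, c("sample_id", "variable", "value"), "scalars.tsv")
  if (!is.numeric(scalars$value))
    stop("scalars.tsv: value must be numeric ('NA' for missing)")
  profiles <- rd("profiles.tsv")
  check_columns(profiles, c("sample_id", "layer", "feature_id", "count"),
                "profiles.tsv")
  if (!is.numeric(profiles$count))
    stop("profiles.tsv: count must be numeric")

  if (!is.null(panel)) {
    bad <- setdiff(unique(scalars$variable),
                   panel$name[panel$dimensionality == "low"])
    if (length(bad))
      stop(sprintf("unknown scalar variable(s) not in the panel: %s",
                   paste(bad, collapse = ", ")))
    bad <- setdiff(unique(profiles$layer),
                   panel$name[panel$dimensionality == "high"])
    if (length(bad))
      stop(sprintf("unknown profile layer(s) not in the panel: %s",
                   paste(bad, collapse = ", ")))
  }

  out <- list(samples = samples, scalars = scalars, profiles = profiles)
  if (file.exists(file.path(dir, "genes.tsv"))) {
    out$genes <- rd("genes.tsv")
    check_columns(out$genes, c("sample_id", "gene_id", "count"), "genes.tsv")
    out$annotation <- rd("gene_annotation.tsv")
    check_columns(out$annotation, c("gene_id", "family"),
                  "gene_annotation.tsv")
  }
  class(out) <- "cohort"
  out
}

#' Run the full perturbation/resilience pipeline
#'
#' Drives every analysis stage over a cohort: pre-treatment variance
#' components, distances from baseline with pre-treatment normalisation,
#' per-subject summaries (maximal perturbation/resilience, standardised
#' AUCs), the Wilcoxon battery against the null references, and the four
#' Spearman correlograms. All outputs are written as TSV under `out_dir`
#' together with `run_log.tsv`, which records every exclusion and fallback
#' (baseline fallback, cohort-median normaliser, window-end substitution)
#' with a machine-readable reason code. The run is deterministic: the
#' analysis stages draw no random numbers.
#'
#' @param cohort A `cohort` list, or a directory to [read_cohort()] from.
#' @param out_dir Output directory.
#' @param panel Variable panel (default [default_panel()]).
#' @param alpha Two-sided significance level.
#' @param resilience_days Late follow-up window (default 15, 30, 90).
#' @return Invisibly, a list with `variability`, `distances`, `summaries`,
#'   `tests`, `correlograms` (list of four), and `log`.
#' @export
run_pipeline <- function(cohort, out_dir, panel = default_panel(),
                         alpha = 0.05, resilience_days = c(15, 30, 90)) {
  if (is.character(cohort)) cohort <- read_cohort(cohort, panel = panel)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  variability <- variability_table(cohort, panel)
  distances <- compute_distances(cohort, panel)
  summaries <- summarise_trajectories(distances, cohort,
                                      resilience_days = resilience_days)
  tests <- wilcoxon_battery(distances, summaries)
  modes <- c("perturbation", "resilience", "baseline_vs_perturbation",
             "baseline_vs_resilience")
  correlograms <- lapply(modes, function(m)
    correlogram(summaries, mode = m, alpha = alpha))
  names(correlograms) <- modes

  write_tsv(variability, file.path(out_dir, "variability.tsv"))
  dist_out <- distances
  attr(dist_out, "log") <- NULL
  write_tsv(dist_out, file.path(out_dir, "distances.tsv"))
  summ_out <- summaries
  attr(summ_out, "log") <- NULL
  write_tsv(summ_out, file.path(out_dir, "summaries.tsv"))
  write_tsv(tests, file.path(out_dir, "tests.tsv"))
  for (m in modes)
    write_tsv(correlograms[[m]]$results,
              file.path(out_dir, sprintf("correlogram_%s.tsv", m)))
  log <- attr(summaries, "log")
  write_tsv(log, file.path(out_dir, "run_log.tsv"))

  invisible(list(variability = variability, distances = distances,
                 summaries = summaries, tests = tests,
                 correlograms = correlograms, log = log))
}
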