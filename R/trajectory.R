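#' @importFrom stats cor complete.cases
NULL

#' Select the baseline sampling day for a subject
#'
#' The baseline sample is the day -1 sample; if missing, day -7; if that is
#' also missing, day -15.
#'
#' @param days_present Integer vector of nominal days at which the subject
#'   has a usable sample.
#' @param candidates Preference-ordered candidate days.
#' @return The selected nominal day. Errors (condition class
#'   `resiliome_no_baseline`) when no pre-treatment sample exists; callers
#'   exclude the subject and log the reason.
#' @export
select_baseline <- function(days_present, candidates = c(-1L, -7L, -15L)) {
  for (d in candidates) if (d %in% days_present) return(as.integer(d))
  stop(structure(
    class = c("resiliome_no_baseline", "error", "condition"),
    list(message = "no pre-treatment sample; subject excluded",
         call = sys.call(-1))))
}

#' Signed change from baseline of a scalar variable
#'
#' `transform(value) - transform(baseline_value)`, with `transform` log10
#' or identity. Non-positive values under log10 yield `NA` with a warning.
#'
#' @param value,baseline_value Values on the natural scale.
#' @param transform `"log10"` or `"identity"`.
#' @return Signed change on the analysis scale (vectorised over `value`).
#' @export
scalar_change <- function(value, baseline_value,
                          transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(value - baseline_value)
  bad <- !is.na(value) & value <= 0
  if ((!is.na(baseline_value) && baseline_value <= 0) || any(bad)) {
    warning("non-positive value under log10 transform; change set to NA")
    if (!is.na(baseline_value) && baseline_value <= 0)
      return(rep(NA_real_, length(value)))
    value[bad] <- NA
  }
  log10(value) - log10(baseline_value)
}

#' Structure distance between two abundance profiles
#'
#' Spearman's rank correlation `s` of the two profiles over their shared
#' support (features with nonzero abundance in at least one profile; shared
#' absences carry no rank information and are excluded), with mid-ranks for
#' ties; the raw distance is `1 - s^2`, which is 0 for identical (or
#' exactly rank-reversed) structures and grows towards 1 as the structures
#' decouple.
#'
#' @param profile,baseline_profile Nonnegative abundance vectors of equal
#'   length (aligned features).
#' @return List with `s` and `raw_distance`, both `NA` when the support has
#'   fewer than 3 features or a profile has zero rank variance.
#' @export
structure_distance <- function(profile, baseline_profile) {
  stopifnot(length(profile) == length(baseline_profile))
  keep <- !is.na(profile) & !is.na(baseline_profile)
  p <- profile[keep]; q <- baseline_profile[keep]
  support <- p > 0 | q > 0
  if (sum(support) < 3)
    return(list(s = NA_real_, raw_distance = NA_real_))
  p <- p[support]; q <- q[support]
  if (length(unique(p)) < 2 || length(unique(q)) < 2)
    return(list(s = NA_real_, raw_distance = NA_real_))
  s <- cor(p, q, method = "spearman")
  list(s = s, raw_distance = 1 - s^2)
}

#' Delay-standardised trapezoidal area under the curve
#'
#' Trapezoidal integral of a post-treatment series over actual collection
#' times, anchored at `t = 0` with value `anchor` (0 for signed changes, 1
#' for normalised distances), up to the actual time `T` of the last sample
#' in the window. The integral is standardised to the nominal window length
#' by multiplying by `window_end / T`, so a flat null series integrates
#' exactly to `anchor * window_end` whatever the collection delays.
#'
#' @param times Actual collection times (> 0) of the points in the window.
#' @param values Metric values at those times; `NA` pairs are dropped.
#' @param window_end Nominal window end (10 or 30 days).
#' @param anchor Value assumed at `t = 0`.
#' @return Standardised AUC, or `NA` when no point is available.
#' @export
auc_standardised <- function(times, values, window_end, anchor) {
  keep <- !is.na(times) & !is.na(values)
  times <- times[keep]; values <- values[keep]
  if (length(times) == 0) return(NA_real_)
  o <- order(times)
  t <- c(0, times[o]); v <- c(anchor, values[o])
  integral <- sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
  integral * window_end / max(times)
}

#' Maximal perturbation of a normalised distance series
#'
#' The maximal normalised distance from baseline observed between baseline
#' and day 10 (nominal days in (0, 10\]).
#'
#' @param nominal_days,normalised Parallel vectors for one subject-variable
#'   series.
#' @param window Inclusive day window (default `c(1, 10)`).
#' @return Maximum, or `NA` when no usable point falls in the window.
#' @export
max_perturbation <- function(nominal_days, normalised, window = c(1, 10)) {
  keep <- !is.na(normalised) & nominal_days >= window[1] &
    nominal_days <= window[2]
  if (!any(keep)) return(NA_real_)
  max(normalised[keep])
}

#' Maximal resilience of a normalised distance series
#'
#' The minimal normalised distance from baseline observed on the late
#' follow-up days (15, 30 or 90); smaller values mean a closer return to
#' the baseline state, i.e. more resilience.
#'
#' @param nominal_days,normalised Parallel vectors for one subject-variable
#'   series.
#' @param days Late follow-up days considered.
#' @return Minimum, or `NA` when no usable point falls on those days.
#' @export
max_resilience <- function(nominal_days, normalised,
                           days = c(15, 30, 90)) {
  keep <- !is.na(normalised) & nominal_days %in% days
  if (!any(keep)) return(NA_real_)
  min(normalised[keep])
}

# internal: append a log row
add_log <- function(log, subject_id, variable, code, detail = "") {
  rbind(log, data.frame(subject_id = subject_id, variable = variable,
                        code = code, detail = detail,
                        stringsAsFactors = FALSE))
}

#' Raw and normalised distances from baseline for a whole cohort
#'
#' For every variable of the panel and every subject: selects the baseline
#' sample (day -1, else -7, else -15), computes the change from baseline on
#' the analysis scale (low-dimensional variables; raw distance = absolute
#' change) or the `1 - s^2` structure distance (high-dimensional layers),
#' then normalises each subject's distances by the mean of its own raw
#' distances at the pre-treatment days that are present and are not the
#' baseline day. Subjects without such pre-treatment distances fall back to
#' the cohort median of the other subjects' normalisers for that variable.
#' A zero normaliser leaves the normalised distances undefined (`NA`).
#'
#' @param cohort A `cohort` list (`samples`, `scalars`, `profiles`), e.g.
#'   from [simulate_cohort()] or [read_cohort()].
#' @param panel Variable panel data frame (see [default_panel()]).
#' @param pretreatment_days Days eligible for the normaliser (default -7
#'   and -15).
#' @return Data frame with one row per subject x variable x non-baseline
#'   sampling day: `variable`, `dimensionality`, `subject_id`,
#'   `nominal_day`, `collection_time`, `s`, `signed_change`, `raw`,
#'   `normalised`, `baseline_day`, `normaliser`, `normaliser_source`. An
#'   attribute `"log"` records every exclusion or fallback with a reason
#'   code.
#' @export
compute_distances <- function(cohort, panel = default_panel(),
                              pretreatment_days = c(-7L, -15L)) {
  samples <- cohort$samples
  log <- data.frame(subject_id = character(0), variable = character(0),
                    code = character(0), detail = character(0),
                    stringsAsFactors = FALSE)
  pieces <- list()

  for (k in seq_len(nrow(panel))) {
    var <- panel$name[k]
    dim_k <- panel$dimensionality[k]

    if (dim_k == "low") {
      dat <- merge(cohort$scalars[cohort$scalars$variable == var, ],
                   samples, by = "sample_id")
      if (nrow(dat) == 0) next
      tr <- panel$transform[k]
      rows_list <- list()
      for (subj in unique(samples$subject_id)) {
        d <- dat[dat$subject_id == subj & !is.na(dat$value), ]
        if (tr == "log10") {
          bad <- d$value <= 0
          if (any(bad)) {
            log <- add_log(log, subj, var, "nonpositive_log10",
                           paste(d$nominal_day[bad], collapse = ","))
            d <- d[!bad, ]
          }
        }
        bday <- tryCatch(select_baseline(d$nominal_day),
                         resiliome_no_baseline = function(e) NA_integer_)
        if (is.na(bday)) {
          log <- add_log(log, subj, var, "no_baseline_sample")
          next
        }
        if (bday != -1L)
          log <- add_log(log, subj, var, "baseline_fallback",
                         sprintf("day %d used as baseline", bday))
        v0 <- d$value[d$nominal_day == bday]
        rest <- d[d$nominal_day != bday, ]
        if (nrow(rest) == 0) next
        chg <- suppressWarnings(scalar_change(rest$value, v0, tr))
        rows_list[[subj]] <- data.frame(
          variable = var, dimensionality = "low", subject_id = subj,
          nominal_day = rest$nominal_day,
          collection_time = rest$collection_time, s = NA_real_,
          signed_change = chg, raw = abs(chg),
          baseline_day = bday, stringsAsFactors = FALSE)
      }
      rows <- do.call(rbind, rows_list)
    } else {
      prof <- cohort$profiles[cohort$profiles$layer == var, ]
      if (nrow(prof) == 0) next
      prof <- merge(prof, samples, by = "sample_id")
      rows_list <- list()
      for (subj in unique(samples$subject_id)) {
        d <- prof[prof$subject_id == subj, ]
        if (nrow(d) == 0) next
        days <- sort(unique(d$nominal_day))
        bday <- tryCatch(select_baseline(days),
                         resiliome_no_baseline = function(e) NA_integer_)
        if (is.na(bday)) {
          log <- add_log(log, subj, var, "no_baseline_sample")
          next
        }
        if (bday != -1L)
          log <- add_log(log, subj, var, "baseline_fallback",
                         sprintf("day %d used as baseline", bday))
        mat <- tapply(d$count, list(d$feature_id, d$nominal_day), sum)
        base_prof <- mat[, as.character(bday)]
        other_days <- setdiff(days, bday)
        res <- lapply(other_days, function(day) {
          sd_ <- structure_distance(mat[, as.character(day)], base_prof)
          ct <- d$collection_time[d$nominal_day == day][1]
          data.frame(variable = var, dimensionality = "high",
                     subject_id = subj, nominal_day = day,
                     collection_time = ct, s = sd_$s, signed_change = NA_real_,
                     raw = sd_$raw_distance, baseline_day = bday,
                     stringsAsFactors = FALSE)
        })
        rows_list[[subj]] <- do.call(rbind, res)
      }
      rows <- do.call(rbind, rows_list)
    }
    if (is.null(rows)) next

    # per-subject normaliser from non-baseline pre-treatment days
    norm_tab <- lapply(split(rows, rows$subject_id), function(r) {
      pre <- r$raw[r$nominal_day %in% pretreatment_days &
                     r$nominal_day != r$baseline_day[1] & !is.na(r$raw)]
      data.frame(subject_id = r$subject_id[1],
                 normaliser = if (length(pre)) mean(pre) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    norm_tab <- do.call(rbind, norm_tab)
    own <- !is.na(norm_tab$normaliser)
    fallback <- if (any(own)) median(norm_tab$normaliser[own]) else NA_real_
    norm_tab$normaliser_source <-
      ifelse(own, "own_pretreatment", "cohort_median")
    for (i in which(!own)) {
      log <- add_log(log, norm_tab$subject_id[i], var,
                     "cohort_median_normaliser")
      norm_tab$normaliser[i] <- fallback
    }
    rows <- merge(rows, norm_tab, by = "subject_id", sort = FALSE)
    zero <- !is.na(rows$normaliser) & rows$normaliser == 0
    if (any(zero))
      for (subj in unique(rows$subject_id[zero]))
        log <- add_log(log, subj, var, "zero_normaliser")
    rows$normalised <- ifelse(is.na(rows$normaliser) | rows$normaliser == 0,
                              NA_real_, rows$raw / rows$normaliser)
    pieces[[var]] <- rows
  }

  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$variable, out$subject_id, out$nominal_day),
             c("variable", "dimensionality", "subject_id", "nominal_day",
               "collection_time", "s", "signed_change", "raw", "normalised",
               "baseline_day", "normaliser", "normaliser_source")]
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Per-subject trajectory summaries
#'
#' Condenses the distance series into the per-subject, per-variable summary
#' used by the correlation analyses: the untransformed baseline value
#' (low-dimensional variables), the maximal perturbation (maximal
#' normalised distance up to day 10), the maximal resilience (minimal
#' normalised distance on days 15/30/90) and the delay-standardised
#' AUC_D0-D10 and AUC_D0-D30. AUCs use the signed change anchored at 0 for
#' low-dimensional variables and the normalised distance anchored at 1 for
#' high-dimensional ones, following the two reference conventions (0 vs
#' window length). When the day-10 (or day-30) sample is missing the window
#' ends at the latest available sample within the window; this substitution
#' is logged.
#'
#' @param distances Output of [compute_distances()].
#' @param cohort The cohort the distances came from (for baseline values).
#' @param resilience_days Late follow-up days (default 15, 30, 90).
#' @param auc_windows Nominal AUC window ends (default 10 and 30).
#' @return Data frame with one row per subject x variable: `subject_id`,
#'   `variable`, `dimensionality`, `baseline_day`, `baseline_value`,
#'   `max_perturbation`, `max_resilience`, `auc_d0_d10`, `auc_d0_d30`,
#'   with a `"log"` attribute extending the distances log.
#' @export
summarise_trajectories <- function(distances, cohort,
                                   resilience_days = c(15, 30, 90),
                                   auc_windows = c(10, 30)) {
  log <- attr(distances, "log")
  if (is.null(log))
    log <- data.frame(subject_id = character(0), variable = character(0),
                      code = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  if (length(resilience_days) == 0)
    warning("empty resilience window; max_resilience will be all NA")

  scal <- merge(cohort$scalars, cohort$samples, by = "sample_id")
  groups <- split(distances,
                  list(distances$variable, distances$subject_id),
                  drop = TRUE)
  out <- lapply(groups, function(r) {
    var <- r$variable[1]; subj <- r$subject_id[1]
    high <- r$dimensionality[1] == "high"
    bday <- r$baseline_day[1]
    bval <- NA_real_
    if (!high) {
      hit <- scal$value[scal$variable == var & scal$subject_id == subj &
                          scal$nominal_day == bday]
      if (length(hit)) bval <- hit[1]
    }
    aucs <- vapply(auc_windows, function(w) {
      inw <- r$nominal_day > 0 & r$nominal_day <= w
      if (!any(inw)) return(NA_real_)
      if (high)
        auc_standardised(r$collection_time[inw], r$normalised[inw], w, 1)
      else
        auc_standardised(r$collection_time[inw], r$signed_change[inw], w, 0)
    }, numeric(1))
    data.frame(subject_id = subj, variable = var,
               dimensionality = r$dimensionality[1], baseline_day = bday,
               baseline_value = bval,
               max_perturbation = max_perturbation(r$nominal_day,
                                                   r$normalised),
               max_resilience = max_resilience(r$nominal_day, r$normalised,
                                               days = resilience_days),
               auc_d0_d10 = aucs[1], auc_d0_d30 = aucs[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)

  # log window-end substitutions (day-10/day-30 sample missing)
  for (w in auc_windows) {
    for (g in groups) {
      inw <- g$nominal_day > 0 & g$nominal_day <= w
      if (any(inw) && max(g$nominal_day[inw]) < w)
        log <- add_log(log, g$subject_id[1], g$variable[1],
                       "window_end_substituted",
                       sprintf("window %d ends at day %d", w,
                               max(g$nominal_day[inw])))
    }
  }
  out <- out[order(out$variable, out$subject_id), ]
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}
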