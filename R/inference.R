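#' @importFrom stats p.adjust pt sd wilcox.test var
#' @importFrom utils combn
NULL

#' Between- and within-subject variance components
#'
#' Fits the random-intercept model `y_ij = mu + b_i + e_ij` by REML
#' (`lme4::lmer`) to repeated pre-treatment measures on the analysis scale
#' and reports the between-subject SD (SD of the random effect), the
#' within-subject SD (residual SD) and their coefficients of variation,
#' `100 * SD / |mu|`. Inputs where every subject's values are identical
#' (zero residual variance) are handled directly: the within SD is 0 and
#' the between SD is the SD of the subject means.
#'
#' @param values Numeric measurements on the analysis scale.
#' @param subject Subject identifier per measurement.
#' @param variable Optional variable name carried into the result.
#' @return Data frame (one row) with `variable`, `n_subjects`, `n_obs`,
#'   `mean`, `between_sd`, `between_cv_pct`, `within_sd`, `within_cv_pct`.
#' @examples
#' vc <- variance_components(c(1, 1.2, 2, 2.1, 3, 3.3),
#'                           c("a", "a", "b", "b", "c", "c"))
#' @export
variance_components <- function(values, subject, variable = NA_character_) {
  keep <- !is.na(values) & !is.na(subject)
  values <- values[keep]; subject <- as.character(subject[keep])
  if (length(unique(subject)) < 2) stop("need at least 2 subjects")
  reps <- table(subject)
  if (!any(reps >= 2))
    stop("within-subject SD undefined: all subjects single-sampled")

  within_ss <- sum(tapply(values, subject, function(v)
    sum((v - mean(v))^2)))
  if (within_ss == 0) {
    means <- tapply(values, subject, mean)
    mu <- mean(means)
    between_sd <- sd(means)
    within_sd <- 0
  } else {
    df <- data.frame(y = values, subject = subject)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | subject), data = df, REML = TRUE)))
    mu <- unname(lme4::fixef(fit)[1])
    vc <- lme4::VarCorr(fit)
    between_sd <- unname(attr(vc$subject, "stddev"))
    within_sd <- attr(vc, "sc")
  }
  data.frame(variable = variable,
             n_subjects = length(unique(subject)),
             n_obs = length(values), mean = mu,
             between_sd = between_sd,
             between_cv_pct = 100 * between_sd / abs(mu),
             within_sd = within_sd,
             within_cv_pct = 100 * within_sd / abs(mu),
             stringsAsFactors = FALSE)
}

#' Pre-treatment variability table for a cohort
#'
#' Applies [variance_components()] to the pre-treatment samples (nominal
#' day < 0) of every low-dimensional variable of the panel, on the analysis
#' scale (log10 where the panel says so).
#'
#' @param cohort A `cohort` list.
#' @param panel Variable panel (see [default_panel()]).
#' @return Data frame, one row per variable, in the panel's order.
#' @export
variability_table <- function(cohort, panel = default_panel()) {
  dat <- merge(cohort$scalars, cohort$samples, by = "sample_id")
  dat <- dat[dat$nominal_day < 0 & !is.na(dat$value), ]
  low <- panel[panel$dimensionality == "low", ]
  out <- lapply(seq_len(nrow(low)), function(i) {
    d <- dat[dat$variable == low$name[i], ]
    if (nrow(d) == 0) return(NULL)
    y <- if (low$transform[i] == "log10") log10(d$value) else d$value
    variance_components(y, d$subject_id, variable = low$name[i])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-sample Wilcoxon signed-rank test against a reference value
#'
#' Two-sided signed-rank test of `values - reference` against a symmetric
#' null centred at zero. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment); the null distribution is exact for at
#' most 25 remaining untied differences and a normal approximation with
#' continuity correction otherwise.
#'
#' @param values Numeric vector (`NA`s dropped).
#' @param reference Reference value (0 for changes from baseline; 1, 10 or
#'   30 for normalised distances and their AUCs).
#' @return List with `statistic` (V), `p_value` and `n` (non-zero
#'   differences used). All-zero differences give `p = 1` with a warning.
#' @export
wilcoxon_vs_reference <- function(values, reference = 0) {
  d <- values[!is.na(values)] - reference
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences equal the reference; p = 1")
    return(list(statistic = NA_real_, p_value = 1, n = 0L))
  }
  ht <- suppressWarnings(wilcox.test(d, mu = 0, exact = n <= 25,
                                     correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n)
}

#' Two-group Wilcoxon rank-sum test
#'
#' Compares a metric between the two treatment arms (e.g. ceftriaxone vs
#' cefotaxime); exact null distribution for small untied samples, normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric vectors for the two groups (`NA`s dropped).
#' @return List with `statistic` (W), `p_value`, `n_x`, `n_y`.
#' @export
wilcoxon_two_group <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups need at least one value")
  ht <- suppressWarnings(wilcox.test(x, y,
                                     exact = length(x) + length(y) <= 50,
                                     correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_x = length(x), n_y = length(y))
}

# all permutations of 1..n as an (n!) x n integer matrix, built
# incrementally by inserting n at every position
all_permutations <- function(n) {
  P <- matrix(1L, 1, 1)
  for (k in seq_len(n)[-1]) {
    m <- nrow(P)
    blocks <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- P[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= k - 1) P[, pos:(k - 1), drop = FALSE]
               else P[, 0, drop = FALSE]
      blocks[[pos]] <- cbind(left, k, right, deparse.level = 0)
    }
    P <- do.call(rbind, blocks)
  }
  P
}

#' Spearman correlation test
#'
#' Mid-rank Spearman correlation with pairwise-complete handling of
#' missing values. The two-sided p-value against rho = 0 comes from full
#' permutation enumeration for at most `exact_max` pairs and from the
#' t-approximation `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees
#' of freedom otherwise.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated (default 9).
#' @return List with `rho`, `p_value`, `n` (complete pairs) and `method`.
#'   Zero rank variance in either vector gives `rho = NA`.
#' @export
spearman_test <- function(x, y, exact_max = 9) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("zero rank variance; rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  rho <- cor(x, y, method = "spearman")
  if (n <= exact_max) {
    rx <- rank(x); ry <- rank(y)
    P <- all_permutations(n)
    M <- matrix(ry[P], nrow = nrow(P))
    cross <- as.vector(M %*% rx)
    rho_all <- (cross / n - mean(rx) * mean(ry)) /
      (sd(rx) * sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, applied once over all tests of
#' a given analysis (global correction).
#'
#' @param p Vector of p-values in \[0, 1\] (`NA`s passed through).
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Format a significant-test fraction
#'
#' Renders "k of m tests significant" the way cohort reports print it,
#' e.g. `format_signif_fraction(16, 136)` gives `"16 (11.8%)"`.
#'
#' @param k Number significant.
#' @param m Number of tests.
#' @return Character scalar `"k (x.x%)"`.
#' @export
format_signif_fraction <- function(k, m) {
  sprintf("%d (%s%%)", k, formatC(100 * k / m, format = "f", digits = 1))
}

#' Spearman correlogram over a metric panel
#'
#' For modes `"perturbation"` and `"resilience"`: Spearman correlation of
#' the per-subject maximal perturbation (resp. maximal resilience) between
#' every unordered pair of panel metrics (the default 17-metric panel gives
#' 136 pairs). For modes `"baseline_vs_perturbation"` and
#' `"baseline_vs_resilience"`: the full rectangular grid of untransformed
#' baseline values of the low-dimensional variables against the outcome of
#' every metric. Missing values are dropped pairwise (`n_pairs` recorded);
#' p-values are BH-adjusted globally over the mode.
#'
#' @param summary Output of [summarise_trajectories()].
#' @param mode One of `"perturbation"`, `"resilience"`,
#'   `"baseline_vs_perturbation"`, `"baseline_vs_resilience"`.
#' @param metrics Optional metric subset (default: all panel variables in
#'   `summary`).
#' @param alpha Two-sided significance level (default 0.05).
#' @param exact_max Passed to [spearman_test()].
#' @return Object of class `correlogram`: list with `results` (long data
#'   frame: `metric_x`, `metric_y`, `rho`, `n_pairs`, `p_value`,
#'   `p_adjusted`, `significant`, `significant_bh`), `mode`, `alpha`,
#'   `n_tests`, `n_significant`, `n_significant_bh`.
#' @export
correlogram <- function(summary,
                        mode = c("perturbation", "resilience",
                                 "baseline_vs_perturbation",
                                 "baseline_vs_resilience"),
                        metrics = NULL, alpha = 0.05, exact_max = 9) {
  mode <- match.arg(mode)
  outcome_col <- if (grepl("resilience", mode)) "max_resilience"
                 else "max_perturbation"
  if (is.null(metrics)) metrics <- unique(summary$variable)
  subjects <- sort(unique(summary$subject_id))
  wide <- function(col, vars) {
    m <- matrix(NA_real_, length(subjects), length(vars),
                dimnames = list(subjects, vars))
    s <- summary[summary$variable %in% vars, ]
    m[cbind(match(s$subject_id, subjects), match(s$variable, vars))] <-
      s[[col]]
    m
  }
  out_mat <- wide(outcome_col, metrics)

  if (mode %in% c("perturbation", "resilience")) {
    if (length(metrics) < 2) stop("need at least 2 metrics")
    pairs <- combn(metrics, 2)
    xs <- pairs[1, ]; ys <- pairs[2, ]
    x_mat <- out_mat; y_mat <- out_mat
  } else {
    base_vars <- unique(summary$variable[summary$dimensionality == "low"])
    x_mat <- wide("baseline_value", base_vars)
    y_mat <- out_mat
    grid <- expand.grid(x = base_vars, y = metrics,
                        stringsAsFactors = FALSE)
    xs <- grid$x; ys <- grid$y
  }

  rows <- lapply(seq_along(xs), function(i) {
    res <- tryCatch(
      suppressWarnings(spearman_test(x_mat[, xs[i]], y_mat[, ys[i]],
                                     exact_max = exact_max)),
      error = function(e) list(rho = NA_real_, p_value = NA_real_,
                               n = sum(complete.cases(x_mat[, xs[i]],
                                                      y_mat[, ys[i]]))))
    data.frame(metric_x = xs[i], metric_y = ys[i], rho = res$rho,
               n_pairs = res$n, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$p_adjusted <- bh_adjust(results$p_value)
  results$significant <- !is.na(results$p_value) & results$p_value < alpha
  results$significant_bh <- !is.na(results$p_adjusted) &
    results$p_adjusted < alpha

  structure(list(results = results, mode = mode, alpha = alpha,
                 n_tests = nrow(results),
                 n_significant = sum(results$significant),
                 n_significant_bh = sum(results$significant_bh)),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("correlogram [%s]: %d tests; significant at alpha = %g: %s; after BH: %s\n",
              x$mode, x$n_tests, x$alpha,
              format_signif_fraction(x$n_significant, x$n_tests),
              format_signif_fraction(x$n_significant_bh, x$n_tests)))
  invisible(x)
}

#' Wilcoxon test battery for a cohort
#'
#' One-sample signed-rank tests of the perturbation metrics against their
#' null references, per variable: the change from baseline (low) or
#' normalised distance (high) at fixed nominal days against 0 (low) or 1
#' (high), and the standardised AUC_D0-D10 / AUC_D0-D30 against 0 (low) or
#' the window length 10 / 30 (high). BH adjustment is applied globally
#' over the battery.
#'
#' @param distances Output of [compute_distances()].
#' @param summaries Output of [summarise_trajectories()].
#' @param days Fixed nominal days tested (default 4, 7, 10, 30, 90).
#' @return Data frame: `variable`, `metric`, `reference`, `n`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
wilcoxon_battery <- function(distances, summaries,
                             days = c(4, 7, 10, 30, 90)) {
  rows <- list()
  for (var in unique(distances$variable)) {
    dv <- distances[distances$variable == var, ]
    high <- dv$dimensionality[1] == "high"
    for (d in days) {
      vals <- if (high) dv$normalised[dv$nominal_day == d]
              else dv$signed_change[dv$nominal_day == d]
      ref <- if (high) 1 else 0
      if (sum(!is.na(vals)) == 0) next
      ht <- suppressWarnings(wilcoxon_vs_reference(vals, ref))
      rows[[length(rows) + 1L]] <-
        data.frame(variable = var, metric = sprintf("day_%d", d),
                   reference = ref, n = ht$n, statistic = ht$statistic,
                   p_value = ht$p_value, stringsAsFactors = FALSE)
    }
    sv <- summaries[summaries$variable == var, ]
    for (w in c(10, 30)) {
      col <- if (w == 10) "auc_d0_d10" else "auc_d0_d30"
      ref <- if (high) w else 0
      vals <- sv[[col]]
      if (sum(!is.na(vals)) == 0) next
      ht <- suppressWarnings(wilcoxon_vs_reference(vals, ref))
      rows[[length(rows) + 1L]] <-
        data.frame(variable = var, metric = sprintf("AUC_D0_D%d", w),
                   reference = ref, n = ht$n, statistic = ht$statistic,
                   p_value = ht$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
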