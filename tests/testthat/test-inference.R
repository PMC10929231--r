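test_that("variance components handle noiseless subjects and match the ANOVA oracle", {
  # identical values within each subject: within SD exactly 0
  vc0 <- variance_components(c(1, 1, 2, 2, 5, 5),
                             c("a", "a", "b", "b", "c", "c"))
  expect_equal(vc0$within_sd, 0)
  expect_equal(vc0$between_sd, sd(c(1, 2, 5)))

  # balanced design: REML equals the method-of-moments estimator
  set.seed(101)
  subj <- rep(sprintf("s%02d", 1:20), each = 3)
  y <- 11.3 + rep(rnorm(20, 0, 0.19), each = 3) + rnorm(60, 0, 0.14)
  vc <- variance_components(y, subj)
  oracle <- anova_vc_oracle(y, subj)
  expect_equal(vc$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(vc$between_sd, oracle$between_sd, tolerance = 1e-6)
  expect_equal(vc$within_sd, oracle$within_sd, tolerance = 1e-6)

  # CV convention: 100 * SD / |mean| on the analysis scale, so a log10
  # bacterial count series at mean ~11.3 with between-SD ~0.19 sits near
  # a 1.7% between-subject CV
  expect_equal(vc$between_cv_pct, 100 * vc$between_sd / abs(vc$mean))
  expect_equal(vc$between_cv_pct, 1.7, tolerance = 0.5)

  expect_error(variance_components(1:3, c("a", "b", "c")), "single-sampled")
  expect_error(variance_components(1:2, c("a", "a")), "2 subjects")
})

test_that("signed-rank test matches sign-flip enumeration and handles degenerate input", {
  # n = 5, all differences positive: exact two-sided p = 2/2^5
  r <- wilcoxon_vs_reference(c(1.2, 0.4, 2.2, 0.6, 1.9), 0)
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$p_value, signed_rank_exact_oracle(c(1.2, 0.4, 2.2, 0.6, 1.9)))

  # values symmetric about the reference: p = 1
  sym <- wilcoxon_vs_reference(c(3, -3, 1, -1, 0.5, -0.5) + 10, 10)
  expect_equal(sym$p_value, 1)

  # random untied fixtures agree with the enumeration oracle
  set.seed(77)
  for (i in 1:5) {
    d <- round(rnorm(8), 3)
    d <- d[d != 0]
    r <- wilcoxon_vs_reference(d, 0)
    expect_equal(r$p_value, signed_rank_exact_oracle(d), tolerance = 1e-12)
  }

  expect_warning(z <- wilcoxon_vs_reference(c(5, 5, 5), 5), "p = 1")
  expect_equal(z$p_value, 1)
})

test_that("two-group rank-sum test matches assignment enumeration", {
  set.seed(12)
  for (i in 1:5) {
    x <- round(rnorm(6, 0.5), 3); y <- round(rnorm(5), 3)
    r <- wilcoxon_two_group(x, y)
    expect_equal(r$p_value, rank_sum_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("spearman test recovers monotone association and its permutation null", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearman_test(x, x^2 + 1)$rho, 1)
  expect_equal(spearman_test(x, -2 * x)$rho, -1)

  set.seed(8)
  for (i in 1:4) {
    a <- rnorm(6); b <- rnorm(6)
    got <- spearman_test(a, b)
    oracle <- spearman_perm_oracle(a, b)
    expect_equal(got$rho, oracle$rho, tolerance = 1e-12)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
    expect_equal(got$method, "exact permutation")
  }

  # pairwise-complete handling and the t-approximation branch
  a <- c(rnorm(30), NA); b <- c(rnorm(30), 1)
  got <- spearman_test(a, b)
  expect_equal(got$n, 30)
  expect_equal(got$method, "t approximation")
  ref <- suppressWarnings(cor.test(a, b, method = "spearman",
                                   exact = FALSE, continuity = FALSE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)

  expect_error(spearman_test(1:3, 3:1), "4 complete pairs")
  expect_warning(flat <- spearman_test(rep(1, 5), 1:5), "rank variance")
  expect_true(is.na(flat$rho))
})

test_that("BH adjustment equals the step-up oracle and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(5)
  p <- runif(25)
  adj <- bh_adjust(p)
  expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("significant-fraction formatting matches the reporting convention", {
  expect_equal(format_signif_fraction(16, 136), "16 (11.8%)")
  expect_equal(format_signif_fraction(7, 136), "7 (5.1%)")
  expect_equal(format_signif_fraction(0, 10), "0 (0.0%)")
})

test_that("correlogram tests every unordered metric pair", {
  set.seed(19)
  subjects <- sprintf("s%02d", 1:22)
  fake_summary <- function(metrics) {
    do.call(rbind, lapply(metrics, function(m)
      data.frame(subject_id = subjects, variable = m,
                 dimensionality = "low", baseline_day = -1,
                 baseline_value = rnorm(22),
                 max_perturbation = rnorm(22), max_resilience = rnorm(22),
                 auc_d0_d10 = NA, auc_d0_d30 = NA,
                 stringsAsFactors = FALSE)))
  }
  cg2 <- correlogram(fake_summary(c("a", "b")), "perturbation")
  expect_equal(cg2$n_tests, 1)

  cg17 <- correlogram(fake_summary(letters[1:17]), "resilience")
  expect_equal(cg17$n_tests, 136)
  expect_true(all(abs(cg17$results$rho) <= 1))
  expect_true(all(cg17$results$p_adjusted >= cg17$results$p_value))
  expect_true(all(cg17$results$n_pairs == 22))
})

test_that("correlogram significance is calibrated on independent metrics", {
  set.seed(4)
  subjects <- sprintf("s%02d", 1:22)
  frac_raw <- numeric(40); any_bh <- logical(40)
  for (r in 1:40) {
    summ <- do.call(rbind, lapply(letters[1:17], function(m)
      data.frame(subject_id = subjects, variable = m,
                 dimensionality = "low", baseline_day = -1,
                 baseline_value = NA_real_, max_perturbation = rnorm(22),
                 max_resilience = NA_real_, auc_d0_d10 = NA,
                 auc_d0_d30 = NA, stringsAsFactors = FALSE)))
    cg <- correlogram(summ, "perturbation")
    frac_raw[r] <- cg$n_significant / cg$n_tests
    any_bh[r] <- cg$n_significant_bh > 0
  }
  expect_gt(mean(frac_raw), 0.02)
  expect_lt(mean(frac_raw), 0.10)
  # under the global null the BH familywise false-discovery rate is <= alpha
  expect_lte(mean(any_bh), 6 / 40)
})

test_that("baseline correlogram modes span the rectangular grid", {
  co <- small_cohort(seed = 2, missingness = 0)
  d <- compute_distances(co, small_panel())
  s <- summarise_trajectories(d, co)
  cg <- correlogram(s, "baseline_vs_perturbation")
  # 2 low-dimensional baselines x 3 panel metrics
  expect_equal(cg$n_tests, 2 * 3)
  expect_true(all(cg$results$metric_x %in%
                    c("bacterial_counts", "bacterial_richness")))
})

test_that("the Wilcoxon battery tests the documented metric-reference pairs", {
  co <- small_cohort(seed = 3, missingness = 0)
  d <- compute_distances(co, small_panel())
  s <- summarise_trajectories(d, co)
  tb <- wilcoxon_battery(d, s)
  expect_setequal(unique(tb$metric),
                  c("day_4", "day_7", "day_10", "day_30", "day_90",
                    "AUC_D0_D10", "AUC_D0_D30"))
  expect_true(all(tb$reference[tb$variable == "bacteria_MGS" &
                                 grepl("day", tb$metric)] == 1))
  expect_true(all(tb$reference[tb$variable == "bacterial_counts"] == 0))
  expect_equal(tb$reference[tb$variable == "bacteria_MGS" &
                              tb$metric == "AUC_D0_D30"], 30)
  expect_equal(tb$p_adjusted, bh_adjust(tb$p_value))
})
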