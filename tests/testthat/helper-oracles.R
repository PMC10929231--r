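# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# One-way balanced ANOVA method-of-moments variance components:
# sigma_w^2 = MSW, sigma_b^2 = (MSB - MSW) / k for k replicates per subject.
anova_vc_oracle <- function(values, subject) {
  k <- unique(table(subject))
  stopifnot(length(k) == 1)  # balanced designs only
  means <- tapply(values, subject, mean)
  grand <- mean(values)
  I <- length(means)
  msb <- k * sum((means - grand)^2) / (I - 1)
  msw <- sum((values - means[as.character(subject)])^2) / (I * (k - 1))
  list(mean = grand, within_sd = sqrt(msw),
       between_sd = sqrt(max(0, (msb - msw) / k)))
}

# Exact one-sample signed-rank p by enumeration of all 2^n sign
# assignments, using R's two-sided tail-doubling convention.
signed_rank_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  centre <- n * (n + 1) / 4
  p <- if (v_obs > centre) mean(v_all >= v_obs) else mean(v_all <= v_obs)
  min(2 * p, 1)
}

# Exact two-sample rank-sum p by enumeration of all group assignments.
rank_sum_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sel <- utils::combn(nx + ny, nx)
  w_all <- apply(sel, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  centre <- nx * ny / 2
  p <- if (w_obs > centre) mean(w_all >= w_obs) else mean(w_all <= w_obs)
  min(2 * p, 1)
}

# Recursive permutation generator (independent of the package's iterative
# one) and full-enumeration Spearman permutation p.
perms_rec <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms_rec(v[-i]), function(p) c(v[i], p))))
}

spearman_perm_oracle <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  rhos <- vapply(perms_rec(seq_along(y)),
                 function(p) cor(x, y[p], method = "spearman"), numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# Benjamini-Hochberg step-up: adj_i = min over j >= i of m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Spearman rho by first principles: mid-ranks computed by counting, then
# Pearson correlation of the ranks.
spearman_rho_oracle <- function(a, b) {
  midrank <- function(v) vapply(v, function(x)
    sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
  ra <- midrank(a); rb <- midrank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# A small crafted cohort with known normalisation arithmetic: one identity
# scalar, four subjects.
#  A: full pre-treatment days; raw distances 2 (day -15) and 4 (day -7),
#     raw 6 at day 4 -> normalised 1.5? no: divisor mean(2,4)=3, 6/3 = 2.
#  B: no -7/-15 samples -> cohort-median fallback.
#  C, D: divisors 1 and 3 so the fallback median over {3, 1, 3} is 3...
# kept simple: divisors of A, C, D are {3, 1, 2} -> median 2.
crafted_cohort <- function() {
  rows <- list(
    # subject, day, value (identity scale)
    c("A", -15, 12), c("A", -7, 14), c("A", -1, 10), c("A", 4, 16),
    c("B", -1, 5), c("B", 4, 9),
    c("C", -15, 21), c("C", -7, 21), c("C", -1, 20), c("C", 4, 26),
    c("D", -15, 31), c("D", -7, 33), c("D", -1, 30), c("D", 4, 37)
  )
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(subject_id = r[1], nominal_day = as.numeric(r[2]),
               value = as.numeric(r[3]), stringsAsFactors = FALSE)))
  df$sample_id <- sprintf("%s_D%g", df$subject_id, df$nominal_day)
  samples <- data.frame(sample_id = df$sample_id,
                        subject_id = df$subject_id, arm = "a",
                        nominal_day = df$nominal_day,
                        collection_time = df$nominal_day,
                        stringsAsFactors = FALSE)
  scalars <- data.frame(sample_id = df$sample_id, variable = "marker",
                        value = df$value, stringsAsFactors = FALSE)
  structure(list(samples = samples, scalars = scalars,
                 profiles = data.frame(sample_id = character(0),
                                       layer = character(0),
                                       feature_id = character(0),
                                       count = numeric(0))),
            class = "cohort")
}

crafted_panel <- function() {
  data.frame(name = "marker", dimensionality = "low",
             transform = "identity", stringsAsFactors = FALSE)
}

# Reduced synthetic cohort used by several suites: 6 subjects, two scalars,
# one bacterial layer.
small_cohort <- function(seed = 11, missingness = 0.1) {
  simulate_cohort(
    n_subjects = 6, missingness_rate = missingness, seed = seed,
    scalar_specs = default_scalar_specs()[c("bacterial_counts",
                                            "bacterial_richness")],
    community_specs = list(bacteria_MGS = community_spec(
      "bacteria_MGS", n_features = 40, sequencing_depth = 5000)),
    resistome = FALSE)
}

small_panel <- function() {
  p <- default_panel()
  p[p$name %in% c("bacterial_counts", "bacterial_richness",
                  "bacteria_MGS"), ]
}
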