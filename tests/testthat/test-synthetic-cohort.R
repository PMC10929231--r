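test_that("design has the full sampling grid and valid jitter", {
  d <- generate_design(22, seed = 1)
  expect_equal(nrow(d$samples), 22 * 12)
  expect_equal(sort(unique(d$samples$nominal_day)), default_schedule())
  expect_true(all(abs(d$samples$collection_time -
                        d$samples$nominal_day) <= 0.25))
  # arms partition the subjects 1:1
  expect_equal(as.integer(sort(table(d$arms))), c(11L, 11L))
  expect_false(any(duplicated(d$samples[, c("subject_id", "nominal_day")])))

  d1 <- generate_design(1, seed = 99)
  expect_equal(nrow(d1$samples), 12)
})

test_that("design is deterministic under a seed and guards the baseline days", {
  d1 <- generate_design(5, missingness_rate = 0.2, seed = 7)
  d2 <- generate_design(5, missingness_rate = 0.2, seed = 7)
  expect_identical(d1$samples, d2$samples)

  # under heavy missingness every subject keeps a pre-treatment sample
  d3 <- generate_design(30, missingness_rate = 0.8, seed = 3)
  pre <- d3$samples[d3$samples$nominal_day < 0, ]
  expect_setequal(unique(pre$subject_id), d3$subjects)

  expect_error(generate_design(3, missingness_rate = 1), "missingness_rate")
  expect_error(generate_design(3, schedule = integer(0)), "nonempty")
  expect_error(generate_design(3, schedule = c(1, 1, 2)), "increasing")
})

test_that("scalar series reduce to subject intercepts without noise or effect", {
  d <- generate_design(4, seed = 2)
  spec <- scalar_spec("x", "identity", baseline_mean = 10,
                      between_sd = 1, within_sd = 0,
                      perturbation_amplitude = 0)
  s <- simulate_scalar_series(d, spec, seed = 5)
  per_subject <- tapply(s$value, s$subject_id, function(v) diff(range(v)))
  expect_true(all(per_subject == 0))

  # log10 reporting: natural-scale values are 10^analysis-scale
  spec_log <- scalar_spec("x", "log10", baseline_mean = 2,
                          between_sd = 0, within_sd = 0,
                          perturbation_amplitude = 0)
  s_log <- simulate_scalar_series(d, spec_log, seed = 5)
  expect_equal(unique(s_log$value), 100)

  expect_identical(simulate_scalar_series(d, spec, seed = 5),
                   simulate_scalar_series(d, spec, seed = 5))
})

test_that("perturbed scalar series peak between days 1 and 10", {
  d <- generate_design(100, seed = 8)
  spec <- scalar_spec("x", "identity", baseline_mean = 100,
                      between_sd = 5, within_sd = 2,
                      perturbation_amplitude = 30, peak_day = 4,
                      recovery_halflife = 10)
  s <- simulate_scalar_series(d, spec, seed = 13)
  peak_day <- vapply(split(s, s$subject_id), function(r) {
    base <- r$value[r$nominal_day == -1]
    post <- r[r$nominal_day > 0, ]
    post$nominal_day[which.max(abs(post$value - base))]
  }, numeric(1))
  expect_true(median(peak_day) >= 1 && median(peak_day) <= 10)
})

test_that("composition counts are compositional and deterministic", {
  d <- generate_design(5, seed = 4)
  spec <- community_spec("bac", n_features = 30, sequencing_depth = 2000)
  p <- simulate_composition_series(d, spec, seed = 21)
  totals <- tapply(p$count, p$sample_id, sum)
  expect_true(all(totals == 2000))
  rel <- tapply(p$count, p$sample_id, function(x) sum(x / sum(x)))
  expect_true(all(abs(rel - 1) < 1e-12))
  expect_identical(p, simulate_composition_series(d, spec, seed = 21))
})

test_that("an unperturbed community keeps its baseline structure", {
  d <- generate_design(10, seed = 6)
  spec <- community_spec("bac", n_features = 50, kill_fraction = 0,
                         kill_depth = 1, sequencing_depth = 1e5)
  p <- simulate_composition_series(d, spec, seed = 9)
  s_by_subject <- vapply(split(p, p$subject_id), function(r) {
    base <- r$count[r$nominal_day == -1]
    day4 <- r$count[r$nominal_day == 4]
    structure_distance(day4, base)$s
  }, numeric(1))
  expect_gte(median(s_by_subject), 0.9)
})

test_that("depletion cuts observed richness and recovery shrinks the distance", {
  # observed richness reacts to depletion only when the sampling depth is
  # shallow relative to community evenness: at depth 500 on an uneven
  # 50-feature community a 100-fold depletion pushes most affected
  # features below the detection threshold
  d <- generate_design(10, seed = 16)
  spec <- community_spec("bac", n_features = 50,
                         baseline_concentration = 0.15,
                         kill_fraction = 0.5, kill_depth = 0.01,
                         recovery_halflife = 5, sequencing_depth = 500)
  p <- simulate_composition_series(d, spec, seed = 17)
  per_subject <- lapply(split(p, p$subject_id), function(r) {
    base_rich <- observed_richness(r$count[r$nominal_day == -1])
    day4_rich <- observed_richness(r$count[r$nominal_day == 4])
    base <- r$count[r$nominal_day == -1]
    d4 <- 1 - structure_distance(r$count[r$nominal_day == 4], base)$s^2
    d30 <- 1 - structure_distance(r$count[r$nominal_day == 30], base)$s^2
    c(drop = (base_rich - day4_rich) / base_rich, d4 = d4, d30 = d30)
  })
  m <- do.call(rbind, per_subject)
  expect_gte(median(m[, "drop"]), 0.25)
  expect_lt(median(m[, "d30"]), median(m[, "d4"]))
})

test_that("resistome bla fraction behaves at its extremes and is enriched after treatment", {
  d <- generate_design(6, seed = 5)

  r0 <- simulate_resistome(d, n_genes = 50, bla_fraction = 0, seed = 1)
  ab0 <- vapply(split(r0$genes, r0$genes$sample_id), function(g)
    betalactamasome_abundance(g$count,
                              r0$annotation$family[match(g$gene_id,
                                                         r0$annotation$gene_id)]),
    numeric(1))
  expect_true(all(ab0 == 0))

  r1 <- simulate_resistome(d, n_genes = 50, bla_fraction = 1, seed = 1)
  ab1 <- vapply(split(r1$genes, r1$genes$sample_id), function(g)
    betalactamasome_abundance(g$count,
                              r1$annotation$family[match(g$gene_id,
                                                         r1$annotation$gene_id)]),
    numeric(1))
  expect_true(all(ab1 == 1))

  rd <- simulate_resistome(d, seed = 2)
  fam <- rd$annotation$family[match(rd$genes$gene_id,
                                    rd$annotation$gene_id)]
  by_day <- function(day) {
    g <- rd$genes[rd$genes$nominal_day == day, ]
    f <- fam[rd$genes$nominal_day == day]
    vapply(split(seq_len(nrow(g)), g$subject_id), function(i)
      betalactamasome_abundance(g$count[i], f[i]), numeric(1))
  }
  expect_gt(median(by_day(4)), median(by_day(-1)))
  expect_identical(simulate_resistome(d, seed = 2)$genes, rd$genes)
})
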