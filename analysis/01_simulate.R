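#!/usr/bin/env Rscript
# Simulate the study cohort: 22 healthy volunteers randomised 1:1 to two
# cephalosporin arms, 12 stool samples each (days -15 to 90), with 5%
# random sample missingness. Writes the cohort tables under
# results/cohort/.

suppressPackageStartupMessages(library(resiliome))

seed <- 20240312
cohort <- simulate_cohort(n_subjects = 22, missingness_rate = 0.05,
                          seed = seed)
write_cohort(cohort, "results/cohort")

cat(sprintf("cohort: %d subjects, %d samples retained of %d scheduled\n",
            length(cohort$design$subjects), nrow(cohort$samples), 22 * 12))
cat(sprintf("scalar variables: %d; community layers: %d; ARD genes: %d\n",
            length(unique(cohort$scalars$variable)),
            length(unique(cohort$profiles$layer)),
            length(unique(cohort$genes$gene_id))))
cat("written to results/cohort/\n")
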