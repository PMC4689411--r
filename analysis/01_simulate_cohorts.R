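#!/usr/bin/env Rscript
# Simulate the two-phase study: a model-building cohort (95 cancer / 81
# control subjects) and an independent blinded model-testing cohort (73 /
# 68), each subject assayed in duplicate at laboratories A and B. The
# workflow runs at a reduced field of 5,000 candidate mass ions (100
# five-second segments x 50 ions) with 50 informative ions at theoretical
# AUC 0.70 — the scaled-down study conditions described in the methods
# vignette.

suppressPackageStartupMessages(library(breathmark))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg_build <- sim_config(n_cancer = 95, n_control = 81, n_segments = 100,
                        ions_per_segment = 50, n_informative = 50,
                        target_auc = 0.70, seed = 20260901)
cohort_build <- simulate_cohort(cfg_build)

cfg_blind <- sim_config(n_cancer = 73, n_control = 68, n_segments = 100,
                        ions_per_segment = 50, n_informative = 50,
                        target_auc = 0.70, seed = 20260902)
cohort_blind <- simulate_blinded_cohort(cfg_blind, cohort_build$truth)

saveRDS(cohort_build, "scratch/cohort_build.rds")
saveRDS(cohort_blind, "scratch/cohort_blind.rds")
data.table::fwrite(cohort_build$truth$informative, "results/ground_truth.csv")
write_sample_meta(rbind(cohort_build$meta, cohort_blind$meta),
                  "results/sample_meta.csv")

message(sprintf("model-building: %d samples (%d subjects), %d candidate ions",
                nrow(cohort_build$meta), nrow(cohort_build$meta) / 2,
                nrow(cohort_build$truth$map)))
message(sprintf("model-testing (blinded): %d samples (%d subjects)",
                nrow(cohort_blind$meta), nrow(cohort_blind$meta) / 2))
message(sprintf("ground truth: %d informative ions, theoretical AUC %.2f",
                nrow(cohort_build$truth$informative), cfg_build$target_auc))
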