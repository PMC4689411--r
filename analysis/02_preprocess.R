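#!/usr/bin/env Rscript
# Normalize every chromatogram to its bromofluorobenzene (m/z 95) internal
# standard and bin records into (5-second segment, unit mass) features.
# Duplicate laboratory samples are pooled as separate rows, as when data
# from two laboratories are combined to develop a single algorithm.

suppressPackageStartupMessages(library(breathmark))

cohort_build <- readRDS("scratch/cohort_build.rds")
cohort_blind <- readRDS("scratch/cohort_blind.rds")

fm_build <- cohort_feature_matrix(cohort_build)
fm_blind <- cohort_feature_matrix(cohort_blind)
saveRDS(fm_build, "scratch/fm_build.rds")
saveRDS(fm_blind, "scratch/fm_blind.rds")

summary_dt <- data.table::data.table(
  phase = c("model_building", "model_testing"),
  n_samples = c(nrow(fm_build$values), nrow(fm_blind$values)),
  n_features = c(ncol(fm_build$values), ncol(fm_blind$values)),
  median_nonzero_intensity = c(median(fm_build$values[fm_build$values > 0]),
                               median(fm_blind$values[fm_blind$values > 0]))
)
data.table::fwrite(summary_dt, "results/preprocess_summary.csv")
message(sprintf("binned %d + %d samples into %d features (IS-normalized ratios)",
                nrow(fm_build$values), nrow(fm_blind$values),
                ncol(fm_build$values)))
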