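#!/usr/bin/env Rscript
# Fit the weighted-digital-analysis predictor on the model-building cohort:
# per selected marker a sign (orientation), weight (its C-statistic) and an
# intensity cutoff maximizing Youden's J; a sample's discriminant function
# (DF) is the weighted sum of firing rules. The model is frozen here —
# nothing downstream may alter it.

suppressPackageStartupMessages(library(breathmark))

fm_build <- readRDS("scratch/fm_build.rds")
screen <- readRDS("scratch/screen.rds")

model <- fit_wda(fm_build, selected = screen)
saveRDS(list(model = model, frozen = serialize(model, NULL, version = 2)),
        "scratch/model.rds")
write_wda(model, "results/wda_model.json")

ts <- model$training_summary
data.table::fwrite(data.table::data.table(
  n_rules = model$k, weight_sum = sum(model$rules$weight),
  n_cancer = ts$n_cancer, n_control = ts$n_control,
  c_statistic = ts$c_statistic, crossover_df = ts$crossover_df,
  sensitivity = ts$sensitivity, specificity = ts$specificity
), "results/training_summary.csv")

message(sprintf("fitted %d rules; training C = %.3f, sens %.1f%% / spec %.1f%% at DF = %.2f",
                model$k, ts$c_statistic, 100 * ts$sensitivity,
                100 * ts$specificity, ts$crossover_df))
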