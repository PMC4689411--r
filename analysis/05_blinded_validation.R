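#!/usr/bin/env Rscript
# Blinded validation: apply the frozen predictor to the model-testing cohort
# (labels untouched until DFs are computed), then unblind and report per-lab
# ROC C-statistics, the sensitivity/specificity crossover, and the
# inter-laboratory concordance of duplicate DF values.

suppressPackageStartupMessages(library(breathmark))

fm_blind <- readRDS("scratch/fm_blind.rds")
frozen <- readRDS("scratch/model.rds")

report <- blinded_report(frozen$model, fm_blind, frozen$frozen)
data.table::fwrite(report$per_lab, "results/blinded_performance.csv")
data.table::fwrite(report$concordance$pairs, "results/interlab_df_pairs.csv")

for (i in seq_len(nrow(report$per_lab))) {
  r <- report$per_lab[i]
  message(sprintf("lab %s: C = %.3f; crossover DF = %.2f, sens %.1f%% / spec %.1f%%",
                  r$lab, r$c_statistic, r$crossover_df,
                  100 * r$sensitivity, 100 * r$specificity))
}
message(sprintf("interlab DF concordance r = %.3f (95%% CI %.3f-%.3f, %d pairs)",
                report$concordance$r, report$concordance$ci[1],
                report$concordance$ci[2], report$concordance$n))
saveRDS(report, "scratch/blinded_report.rds")
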