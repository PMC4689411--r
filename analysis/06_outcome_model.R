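#!/usr/bin/env Rscript
# Projected screening outcomes of combining a breath test with low-dose
# chest CT (sensitivity 93.8%, specificity 73.4%) at 1.1% lung-cancer
# prevalence, per million people screened. Two tables: one using the
# published blinded breath-test operating point (sens 70.1% / spec 68.0%),
# one using this workflow's own blinded laboratory-B operating point.

suppressPackageStartupMessages(library(breathmark))

ct <- test_profile("chest CT", 0.938, 0.734)
prev <- 0.011

published <- test_profile("breath (published)", 0.701, 0.680)
oc_pub <- screening_outcome(ct, published, prev)
data.table::fwrite(oc_pub, "results/screening_outcome_published.csv")
print(oc_pub)

report <- readRDS("scratch/blinded_report.rds")
lab_b <- report$per_lab[lab == "B"]
own <- test_profile("breath (this workflow, lab B)",
                    lab_b$sensitivity, lab_b$specificity)
oc_own <- screening_outcome(ct, own, prev)
data.table::fwrite(oc_own, "results/screening_outcome_synthetic.csv")
print(oc_own)

message(sprintf("combined both-positive: specificity %.2f%% (CT alone %.1f%%), PPV %.2f%%",
                100 * oc_pub$spec[3], 100 * ct$spec, 100 * oc_pub$ppv[3]))
message(sprintf("combined either-positive: sensitivity %.2f%% (CT alone %.1f%%)",
                100 * oc_pub$sens[4], 100 * ct$sens))
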