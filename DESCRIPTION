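Package: breathmark
Title: Breath VOC Mass-Ion Biomarker Discovery and Blinded Validation for
    Lung Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discovering and validating breath volatile
    organic compound (VOC) biomarkers of lung cancer from aligned GC-MS
    mass-ion tables. Implements internal-standard (bromofluorobenzene, m/z 95)
    normalization and 5-second retention-time binning of long-form ion tables;
    Monte-Carlo permutation screening of per-ion C-statistics with a
    random-assignment cutoff curve; a weighted digital analysis (WDA)
    discriminant classifier (per-marker cutoff, sign, and C-statistic weight);
    blinded-validation metrics (sensitivity/specificity crossover, ROC
    C-statistic, inter-laboratory concordance of discriminant functions); an
    analytic model of combining a breath test with chest CT in series or
    parallel (sensitivity, specificity, PPV, NPV, expected screening counts);
    and a synthetic cohort generator with known ground truth for calibrating
    and power-testing the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
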