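---
title: "Methods: breath VOC biomarker discovery, WDA classification, and blinded validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath VOC biomarker discovery, WDA classification, and blinded validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
preprocessing model for aligned GC-MS ion tables, the Monte-Carlo
C-statistic screen, the weighted-digital-analysis (WDA) classifier, the
validation metrics, the combined-test screening model, and the synthetic
cohort generator that the test suite uses as its oracle. It also records
the numerical conventions and the design decisions taken where the
underlying methodology leaves room.

## 1. The data and the preprocessing model

The pipeline's input is the output of chromatogram alignment software: per
breath sample, a long-form table of mass-ion records — retention time in
seconds, mass-to-charge ratio m/z, intensity in arbitrary ion-current
units. Peak detection, deconvolution, and spectral library matching are
deliberately upstream of this package: individual mass ions are treated as
features in their own right, which makes the markers robust to co-elution
and to the uncertainty of matching a full spectrum against a library.

Two normalizations anchor everything on the internal standard — a known
quantity of bromofluorobenzene added to every sample, observed through its
m/z-95 fragment:

* **Intensity**: every intensity is divided by the internal-standard
  intensity. Ratios are dimensionless and invariant to the overall sample
  loading (the test suite checks that scaling a whole chromatogram by any
  positive constant leaves the feature matrix unchanged).
* **Retention time**: if a reference retention time for the standard is
  configured, every record's time is multiplied by
  `reference_is_rt / observed_is_rt`. A single anchor compound can support
  no more than this one-point linear rescaling; with `reference_is_rt =
  NULL` (the default) times are left as aligned upstream.

The internal-standard record is located as the maximum-intensity m/z-95
record inside a configurable retention-time window (default: the whole
run, since no canonical elution time can be assumed). A table without such
a record is rejected outright — nothing downstream is meaningful without
the anchor.

Records are then binned into half-open retention-time segments
`[w·k, w·(k+1))`, `k = floor(rt/w)`, with `w = 5` seconds by default, and
keyed by (segment, unit mass). Numerical conventions, each chosen for
determinism:

* fractional m/z rounds **half-up** to unit mass (reported marker masses
  are integers such as 43, 57, 95);
* multiple records in one (sample, segment, m/z) cell are **summed** — ion
  current is additive;
* a feature absent from a sample's table is **0**: absence of signal, not
  missingness;
* segment boundaries are half-open, so a record at exactly 1505 s starts
  segment 301 rather than being double-counted.

Room-air samples can be ingested and are flagged by `sample_kind`, but no
subtraction is applied: there is no principled single-sample subtraction
rule for sorbent-trap background, so environmental control is left to the
study design (breath and room-air collected in the same room). A
`min_prevalence` filter (default 0, i.e. keep everything) can drop
features present in too few samples.

## 2. The Monte-Carlo marker screen

Screening compares **tissue-confirmed cancer** (group 3, status positive)
against **CT-negative controls** (group 1, status negative); groups 2 and
4 and unknown-status samples are excluded from screening and fitting but
still receive predictions. Duplicate samples assayed at two laboratories
enter as separate rows ("pooling"), the convention under which a single
algorithm is developed from both laboratories' data; because duplicates of
one subject are correlated, the effective sample size stays near the
number of subjects, a point that matters for the power analysis in §7.

Each feature's discrimination is its **C-statistic**: the Mann–Whitney
concordance probability (midrank ties counted ½), computed from a rank
matrix so that one ranking per feature serves every label assignment. The
statistic is folded to [0.5, 1] with an orientation sign (+1 elevated in
cancer, −1 depressed); folding matches the screen's count curves, which
start at C = 0.5.

The null reference is built from `n_perm = 40` **random assignments**:
each is one label shuffle, preserving class sizes and shared across all
features, so the inter-feature correlation structure of the null is
preserved (subjects are permuted, never per-ion values). Permuted
C-statistics are folded by default; `fold_random = FALSE` gives the
unfolded alternative, since the folding convention of the original
curve-based procedure is not documented.

On an ascending grid of C values (step 0.01) the screen counts features
with `c_correct ≥ x` and, per permutation, features with permuted C ≥ x.
The **cutoff** `C*` is the smallest grid value where the mean random count
is exactly zero — with 40 permutations, "mean < 1/40" is equivalent to "no
occurrence anywhere". If the random curve never dies the cutoff falls back
to the top of the grid with a warning. The **sigma separation** between
curves is `(count_correct − mean_random)/sd_random`, evaluated at the
largest grid point at or below `C*` where the random-count SD is still
positive (the SD is identically zero wherever the random count is).
Selection keeps features with `c_correct ≥ C*`, ordered by descending
C-statistic with the deterministic tie-break (segment, then m/z),
truncated to `k = 500`. A segment-major ordering (`within_segment = TRUE`)
is available because per-segment ranking is an equally defensible reading;
the eligible set is identical either way.

No formal false-discovery procedure (Benjamini–Hochberg and relatives) is
offered: the random-curve cutoff *is* the method under study.

## 3. The WDA classifier

WDA digitizes each selected marker into a binary vote. A rule is
`(feature, cutoff c, sign s, weight w)`:

* `s` is the marker's orientation from the screen;
* `w` is its C-statistic (configurable to `2C − 1`, which rescales weights
  to [0, 1] and zeroes out chance-level markers);
* `c` maximizes Youden's J (sensitivity + specificity − 1) for the
  single-marker rule `s·(x − c) > 0 ⇒ cancer`, searched over midpoints of
  consecutive distinct observed values. Ties in J break toward the
  **smaller** cutoff; tie detection uses a 1e-9 tolerance so that
  floating-point noise in equal J values cannot flip the choice. Maximum
  accuracy is a defensible alternative criterion; Youden's J is the
  default because it is prevalence-free.

A constant feature has no midpoints; its rule keeps the marker's weight
but never fires (J = 0), and fitting warns. The discriminant function of a
sample is `DF = Σ wᵢ·1[sᵢ(xᵢ − cᵢ) > 0]`, so `0 ≤ DF ≤ Σ wᵢ`. Both the
rule threshold and the DF classification threshold are **strict**
inequalities ("greater than"), so a result exactly at a cutoff scores
negative. A rule feature absent from a test sample's matrix scores as
intensity 0, consistent with the preprocessing's absence semantics.
`predict_df()` consults only feature values — the test suite verifies that
shuffling all metadata leaves predictions bit-identical, which is the
blinding contract.

No other classifier family (logistic regression, trees, SVM) is in scope,
and DF values are not calibrated to probabilities.

## 4. Validation metrics

`perf_curve()` evaluates sensitivity and specificity at every distinct
observed DF value plus 0. The discrete step curves rarely intersect
exactly, so the **crossover** operating point is the cutoff maximizing
sens + spec — the quantity that is maximal where the continuous curves
cross — with ties toward the smaller cutoff. The ROC C-statistic of DF is
computed by the same Mann–Whitney statistic as the screen; an internal
consistency test confirms it equals the trapezoidal area under the
(1 − spec, sens) polyline built from the same grid.

`interlab_concordance()` pairs each subject's laboratory-A and
laboratory-B DF values and reports the Pearson correlation with a
Fisher-z 95% confidence interval (the CI method is a package choice;
subjects missing either replicate are dropped and counted). Fewer than
three pairs, or zero variance in either laboratory, are errors rather
than numbers.

`blinded_report()` enforces the freeze: given the `serialize()` snapshot
taken when the model was frozen, it refuses to score if the model has
drifted by a single byte. Samples with unknown cancer status receive DF
values but never enter the performance metrics.

## 5. The combined-screening outcome model

Two tests A and B with sensitivities/specificities `(sensA, specA)`,
`(sensB, specB)` are combined under conditional independence given
disease status:

* both positive: `sens = sensA·sensB`, `spec = 1 − (1−specA)(1−specB)`;
* either positive: `sens = 1 − (1−sensA)(1−sensB)`, `spec = specA·specB`;
* `PPV = sens·prev / [sens·prev + (1−spec)(1−prev)]`,
  `NPV = spec(1−prev) / [spec(1−prev) + (1−sens)·prev]`;
* expected counts among n screened: `TP = sens·prev·n`,
  `FN = (1−sens)·prev·n`, `TN = spec(1−prev)·n`, `FP = (1−spec)(1−prev)·n`,
  kept as exact fractions internally and rounded only for display.

Conditional independence is the model's load-bearing assumption and is
stated wherever results are reported; correlated test errors, sequential
strategies beyond the two rules, and cost-effectiveness are out of scope.
The default inputs used by the acceptance script are chest CT sensitivity
93.8% and specificity 73.4% with prevalence 1.1% (the National Lung
Screening Trial values) and the breath test's blinded laboratory-B
operating point, sensitivity 70.1% / specificity 68.0% — the pair
consistent with the published combined specificities and sensitivities.
The model's algebra implies two exact reduction identities the tests
check: moving from A alone to "both positive" removes exactly the
fraction `specB` of A's false positives, and moving to "either positive"
removes exactly `sensB` of A's false negatives.

## 6. The synthetic cohort generator

The generator emulates the *statistical structure* of a two-phase,
two-laboratory breath study, and is itself first-class, tested code:

* **Intensity model**: log-normal. Each subject has a latent log intensity
  per ion, `N(baseline, σ_subj²)` with `σ_subj = 0.75` by default; each
  laboratory's measurement adds independent `N(0, σ_lab²)` noise; a
  per-sample loading factor (log-SD 0.2) multiplies every record
  *including the internal standard*, so internal-standard normalization
  removes it exactly — which is precisely what the normalization is for.
  Log-normality is the standard positive, right-skewed, multiplicative
  model for ion abundances; the real intensity distribution is not
  documented, so this is a modelling choice.
* **Effect injection**: a fraction of ions get a log-mean shift `±δ` in
  cancer subjects, direction random with equal probability. δ is
  calibrated through the Gaussian AUC closed form
  `AUC = Φ(δ / (σ√2))` with `σ² = σ_subj² + σ_lab²`, the *per-measurement*
  variance, so the theoretical AUC of an informative ion equals
  `target_auc` exactly for the values the screen actually sees. (Using
  the between-subject SD alone would bias the measured per-ion AUC low by
  about 0.01 at the default SDs; the unit tests verify the closed form to
  < 0.01 at n = 1500 per class.)
* **Replicate correlation**: the between-laboratory correlation of a null
  ion's normalized log intensities is `σ_subj²/(σ_subj² + σ_lab²)`; the
  default `σ_lab = σ_subj·√(1/0.88 − 1)` sets it to 0.88, the replicate
  concordance level the emulated study reported. An optional `lab_bias`
  adds a systematic log-scale offset between laboratories for
  stress-testing.
* **Structure**: defaults mirror the study conditions — 95/81
  cancer/control subjects in the model-building phase (73/68 in blinded
  configurations), 700 segments × 100 ions = 70,000 candidates, 544
  informative at AUC 0.70. The ion map (which m/z sits in which segment)
  is deterministic so that the blinded phase, generated from the same
  `breath_truth`, shares the feature space exactly; retention times sit at
  segment midpoints, emulating *aligned* chromatograms. An
  `informative_mz` option concentrates informative ions on chosen masses
  (e.g. 43/57, alkane-fragment-like) for tests of the marker map.
* **Determinism**: one integer seed; identical configuration gives
  bit-identical cohorts.

What the generator deliberately does **not** simulate: chromatographic
drift and misalignment, co-elution (and hence correlation between ions
from a shared parent VOC), realistic fragmentation patterns, room-air
contamination chemistry, or inter-subject covariates affecting the breath
matrix. Consequently, passing tests demonstrate the pipeline's behavior
under a clean, independent-ion null and known effect sizes — not
performance on real chromatograms. Two concrete consequences are visible
in the acceptance studies (§7): independent planted ions make the blinded
DF *more* discriminating, and the DF-level interlaboratory correlation
*higher*, than the real study's correlated ion clusters produced.

## 7. Problem sizes, calibration, and known limitations

The test suite and acceptance script run scaled-down studies, chosen once
as realistic-but-tractable problem sizes: 2,000 candidate ions (40
segments × 50) for the recovery study and 1,000 for the null-calibration
and concordance studies, each over 20 replicate cohorts at the study's
class sizes, with 40 permutations and k = 500 throughout. The unit tests
use smaller cohorts still, with effect sizes (AUC 0.75–0.9) strong enough
to make their assertions sharp.

Two behaviors of the method at these conditions are worth recording:

* **Recovery at modest effect sizes is intrinsically marginal.** With 50
  planted ions at measured AUC 0.70 and ~176 effective subjects, the
  random-curve cutoff lands near 0.64–0.66 while a planted ion's empirical
  C-statistic is roughly N(0.70, 0.037): the per-ion selection probability
  is ≈ 0.9, so replicates recovering ≥ 90% of planted ions are common but
  not guaranteed. This is a property of cutoff-gated selection at AUC
  0.70, not of the implementation (the C-statistic and the selection rule
  are verified against exhaustive oracles).
* **DF concordance exceeds per-ion concordance.** Summing ~50 independent
  informative votes averages away laboratory noise, and the cancer/control
  separation adds variance shared by both laboratories, so the
  interlaboratory DF correlation measured in the acceptance study runs
  above the generator's per-ion 0.88. A real panel whose markers are
  correlated fragments of a few parent VOCs carries fewer effective
  independent votes and correspondingly noisier DF values.

Other limitations: the WDA reading (binary votes, C-statistic weights,
Youden cutoffs) is this package's explicit interpretation of a briefly
specified method, with each ingredient exposed as a configuration point;
subject-level duplicate pooling risks optimism in training metrics (the
blinded phase, with disjoint subjects, is the honest measure); and the
outcome model's conditional-independence assumption is untestable from
the data the pipeline sees.
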