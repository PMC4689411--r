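test_that("performance curves match hand-computed sensitivity/specificity", {
  dfs <- c(10, 20, 30, 5, 15, 25)
  y <- rep(c(TRUE, FALSE), each = 3)
  pc <- perf_curve(dfs, y)
  expect_equal(pc$auc, 6 / 9)
  expect_identical(pc$cutoffs, c(0, 5, 10, 15, 20, 25, 30))

  # brute-force sweep oracle for the crossover
  sums <- vapply(pc$cutoffs, function(cc) {
    mean(dfs[y] > cc) + mean(dfs[!y] <= cc)
  }, numeric(1))
  expect_equal(pc$crossover$sens + pc$crossover$spec, max(sums))
  expect_equal(pc$crossover$df, pc$cutoffs[which.max(sums)])

  # perfectly separated: AUC 1 and a crossover with sens = spec = 1
  pc2 <- perf_curve(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pc2$auc, 1)
  expect_equal(pc2$crossover$sens, 1)
  expect_equal(pc2$crossover$spec, 1)

  # all DFs equal: chance
  expect_equal(perf_curve(rep(3, 6), y)$auc, 0.5)

  expect_error(perf_curve(1:3, c(TRUE, TRUE, TRUE)),
               class = "breathmark_degenerate_error")
})

test_that("curve identities hold: counts, monotonicity, trapezoidal AUC", {
  set.seed(404)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || all(y)) next
    dfs <- sample(0:20, n, replace = TRUE) / 2 + ifelse(y, 1.5, 0)
    pc <- perf_curve(dfs, y)
    # confusion counts always partition the sample
    expect_true(all(pc$counts$tp + pc$counts$fn + pc$counts$tn + pc$counts$fp == n))
    expect_equal(pc$counts$tp / pc$n_cancer, pc$sens)
    expect_equal(pc$counts$tn / pc$n_control, pc$spec)
    # step curves are monotone in the cutoff
    expect_true(all(diff(pc$sens) <= 0))
    expect_true(all(diff(pc$spec) >= 0))
    # crossover is the global maximum of sens + spec over the grid
    expect_true(all(pc$crossover$sens + pc$crossover$spec >=
                      pc$sens + pc$spec - 1e-12))
    # trapezoidal area under the (1 - spec, sens) polyline equals the
    # Mann-Whitney AUC computed independently from ranks
    x <- c(1, 1 - pc$spec, 0)
    yy <- c(1, pc$sens, 0)
    area <- sum((x[-length(x)] - x[-1]) * (yy[-1] + yy[-length(yy)]) / 2)
    expect_equal(area, cstat(dfs, y)$auc)   # raw, unfolded AUC
  }
})

test_that("interlab concordance pairs subjects and handles degenerate input", {
  meta <- rbind(make_meta(c("a_A", "b_A", "c_A"), c("a", "b", "c"), lab = "A"),
                make_meta(c("a_B", "b_B", "c_B"), c("a", "b", "c"), lab = "B"))
  dfa <- data.frame(sample_id = c("a_A", "b_A", "c_A"), df = c(1, 5, 9))
  dfb_same <- data.frame(sample_id = c("a_B", "b_B", "c_B"), df = c(1, 5, 9))
  expect_equal(interlab_concordance(dfa, dfb_same, meta)$r, 1)

  # affine invariance: B = 2A + 3 exactly
  dfb_aff <- data.frame(sample_id = c("a_B", "b_B", "c_B"), df = 2 * c(1, 5, 9) + 3)
  cc <- interlab_concordance(dfa, dfb_aff, meta)
  expect_equal(cc$r, 1)
  expect_equal(cc$n, 3)

  # subjects missing a replicate are dropped and counted
  meta4 <- rbind(meta, make_meta("d_A", "d", lab = "A"))
  dfa4 <- rbind(dfa, data.frame(sample_id = "d_A", df = 4))
  cc2 <- interlab_concordance(dfa4, dfb_aff, meta4)
  expect_equal(cc2$n, 3)
  expect_equal(cc2$n_dropped, 1)
})

test_that("interlab concordance errors on too few pairs or zero variance", {
  meta <- rbind(make_meta(c("a_A", "b_A"), c("a", "b"), lab = "A"),
                make_meta(c("a_B", "b_B"), c("a", "b"), lab = "B"))
  dfa <- data.frame(sample_id = c("a_A", "b_A"), df = c(1, 2))
  dfb <- data.frame(sample_id = c("a_B", "b_B"), df = c(1, 2))
  expect_error(interlab_concordance(dfa, dfb, meta),
               class = "breathmark_insufficient_data")

  meta3 <- rbind(make_meta(c("a_A", "b_A", "c_A"), c("a", "b", "c"), lab = "A"),
                 make_meta(c("a_B", "b_B", "c_B"), c("a", "b", "c"), lab = "B"))
  dfa3 <- data.frame(sample_id = c("a_A", "b_A", "c_A"), df = c(2, 2, 2))
  dfb3 <- data.frame(sample_id = c("a_B", "b_B", "c_B"), df = c(1, 5, 9))
  expect_error(interlab_concordance(dfa3, dfb3, meta3),
               class = "breathmark_undefined_correlation")
})

test_that("the blinded report reproduces training metrics on training data", {
  cfg <- tiny_sim(n_cancer = 20, n_control = 18, seed = 141)
  co <- simulate_cohort(cfg)
  fm <- cohort_feature_matrix(co)
  sr <- screen_markers(fm, seed = 5, k = 20)
  mod <- fit_wda(fm, selected = sr)
  rep1 <- blinded_report(mod, fm)
  # pooled training metrics live in training_summary; per-lab curves on the
  # same subjects must carry the same DF scale and similar operating points
  pooled <- perf_curve(predict_df(mod, fm)$df, screening_labels(fm$meta))
  expect_equal(pooled$auc, mod$training_summary$c_statistic)
  expect_equal(pooled$crossover$sens, mod$training_summary$sensitivity)
  expect_equal(pooled$crossover$spec, mod$training_summary$specificity)
  expect_identical(sort(rep1$per_lab$lab), c("A", "B"))
  expect_equal(rep1$concordance$n, 38)

  # byte-identical reports on identical inputs
  rep2 <- blinded_report(mod, fm)
  expect_identical(serialize(rep1, NULL, version = 2),
                   serialize(rep2, NULL, version = 2))
})

test_that("a predictor that drifted from its frozen snapshot is rejected", {
  cfg <- tiny_sim(seed = 151)
  fm <- cohort_feature_matrix(simulate_cohort(cfg))
  mod <- fit_wda(fm, selected = screen_markers(fm, seed = 5, k = 10))
  snapshot <- serialize(mod, NULL, version = 2)
  expect_s3_class(blinded_report(mod, fm, snapshot), "blinded_report")
  tampered <- mod
  tampered$rules$weight[1] <- tampered$rules$weight[1] + 0.01
  expect_error(blinded_report(tampered, fm, snapshot),
               class = "breathmark_blinding_violation")
})

test_that("samples with unknown cancer status get DFs but not metrics", {
  cfg <- tiny_sim(n_cancer = 10, n_control = 10, seed = 161)
  co <- simulate_cohort(cfg)
  fm <- cohort_feature_matrix(co)
  mod <- fit_wda(fm, selected = screen_markers(fm, seed = 5, k = 10))
  fm$meta$cancer_status[fm$meta$subject_id == "S0001"] <- "unknown"
  rep1 <- blinded_report(mod, fm)
  expect_equal(unique(rep1$per_lab$n_cancer), 9)       # one subject masked out
  expect_true(all(c("S0001_A", "S0001_B") %in%
                    c(rep1$dfs$A$sample_id, rep1$dfs$B$sample_id)))
})
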