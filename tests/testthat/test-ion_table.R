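test_that("reading locates the internal standard and rounds m/z to unit mass", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,rt,mz,intensity",
               "s1,100.0,95,1e6",
               "s1,100.0,43,2e5",
               "s1,500.0,56.6,1e4"), path)
  t <- read_ion_table(path)
  expect_s3_class(t, "ion_table")
  expect_equal(t$records$intensity[t$is_index], 1e6)
  expect_equal(t$records$mz[t$is_index], 95L)
  expect_true(57L %in% t$records$mz)   # 56.6 rounds half-up to 57
  expect_false(56L %in% t$records$mz)
})

test_that("malformed or invalid ion tables are rejected with classed errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,rt,intensity", "s1,100,5"), path)
  expect_error(read_ion_table(path), class = "breathmark_format_error")

  expect_error(
    ion_table("s1", data.frame(rt = 100, mz = 43, intensity = 10)),
    class = "breathmark_missing_internal_standard"
  )
  expect_error(
    ion_table("s1", data.frame(rt = c(100, 200), mz = c(95, 43),
                               intensity = c(1e6, -1))),
    class = "breathmark_validation_error"
  )
  # IS outside the configured search window is as good as absent
  expect_error(
    ion_table("s1", data.frame(rt = 900, mz = 95, intensity = 1e6),
              preprocess_config(is_rt_window = c(0, 800))),
    class = "breathmark_missing_internal_standard"
  )
})

test_that("ion tables survive a write/read round trip exactly", {
  t <- make_table(intensity = c(1234567.891, 0.000123456789, 3 / 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ion_table(t, path)
  t2 <- read_ion_table(path)
  expect_identical(t2$records$rt, t$records$rt)
  expect_identical(t2$records$mz, t$records$mz)
  expect_identical(t2$records$intensity, t$records$intensity)
  expect_identical(t2$is_index, t$is_index)
})

test_that("normalization divides by the IS, rescales rt, and is idempotent", {
  t <- make_table()
  n1 <- normalize_table(t)
  expect_equal(n1$records$intensity[n1$is_index], 1)
  expect_equal(n1$records$intensity[n1$records$mz == 43], 0.2)
  expect_true(is_normalized(n1))

  # single-point retention-time rescaling: observed IS at 1000 s, reference 1100
  t2 <- make_table(rt = c(1000, 500, 2000))
  cfg <- preprocess_config(reference_is_rt = 1100)
  n2 <- normalize_table(t2, cfg)
  expect_equal(n2$records$rt, c(1100, 550, 2200))

  # already-normalized table (IS intensity 1, IS rt at reference): unchanged
  n3 <- normalize_table(n2, cfg)
  expect_equal(n3$records, n2$records)
})

test_that("normalized intensities are invariant to a global intensity scale", {
  t_raw <- make_table()
  t_scaled <- make_table(intensity = c(1e6, 2e5, 1e4) * 37.5)
  meta <- make_meta("s1")
  fm1 <- bin_to_features(list(normalize_table(t_raw)), meta)
  fm2 <- bin_to_features(list(normalize_table(t_scaled)), meta)
  expect_equal(fm1$values, fm2$values)
})

test_that("binning uses half-open 5 s segments and sums within-cell records", {
  t <- make_table(rt = c(100, 1502, 1505, 700, 700),
                  mz = c(95, 43, 43, 57, 57),
                  intensity = c(1e6, 1e5, 1e5, 1e5, 2e5))
  fm <- bin_to_features(list(normalize_table(t)), make_meta("s1"))
  expect_true("seg300_mz43" %in% fm$features$key)   # floor(1502/5) = 300
  expect_true("seg301_mz43" %in% fm$features$key)   # 1505 starts the next bin
  # two records in (seg 140, mz 57): 0.1 + 0.2
  expect_equal(unname(fm$values["s1", "seg140_mz57"]), 0.3)
})

test_that("binning conserves total normalized intensity and rejects raw tables", {
  cfg <- tiny_sim(n_cancer = 4, n_control = 4, n_informative = 2)
  co <- simulate_cohort(cfg)
  tabs <- lapply(co$tables_a, normalize_table)
  fm <- bin_to_features(tabs, co$meta)
  for (t in tabs) {
    expect_equal(sum(fm$values[t$sample_id, ]), sum(t$records$intensity))
  }
  expect_error(bin_to_features(co$tables_a, co$meta),
               class = "breathmark_state_error")
  expect_error(bin_to_features(tabs, co$meta[1]),
               class = "breathmark_meta_error")
})

test_that("the prevalence filter drops rare features", {
  t1 <- make_table("s1", rt = c(100, 200), mz = c(95, 43), intensity = c(10, 5))
  t2 <- make_table("s2", rt = c(100, 300), mz = c(95, 57), intensity = c(10, 5))
  meta <- rbind(make_meta("s1"), make_meta("s2"))
  tabs <- lapply(list(t1, t2), normalize_table)
  fm_all <- bin_to_features(tabs, meta)
  fm_flt <- bin_to_features(tabs, meta, preprocess_config(min_prevalence = 0.9))
  expect_true(all(c("seg40_mz43", "seg60_mz57") %in% fm_all$features$key))
  # only the IS cell (present in both samples) survives a 90% filter
  expect_identical(fm_flt$features$key, "seg20_mz95")
})

test_that("feature matrices round-trip through CSV bit-exactly", {
  cfg <- tiny_sim(n_cancer = 3, n_control = 3, n_informative = 2)
  fm <- cohort_feature_matrix(simulate_cohort(cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  fm2 <- read_feature_matrix(path)
  expect_identical(fm2$values, fm$values)
  expect_equal(fm2$features, fm$features)
})

test_that("the marker map reports segment midpoints and matches planted truth", {
  # alkane-like truth: informative ions carry m/z 43 and 57
  cfg <- tiny_sim(n_cancer = 30, n_control = 30, n_segments = 8,
                  ions_per_segment = 12, n_informative = 8,
                  target_auc = 0.9, informative_mz = c(43L, 57L), seed = 7)
  co <- simulate_cohort(cfg)
  fm <- cohort_feature_matrix(co)
  sr <- screen_markers(fm, seed = 11, k = 20)
  mm <- export_marker_map(fm, sr)
  expect_equal(mm$rt_mid, sr$selected$segment * 5 + 2.5)
  # the dominant masses among selected ions are the planted fragment masses
  expect_true(all(sort(unique(co$truth$informative$mz)) %in% c(43L, 57L)))
  top_mz <- names(sort(table(mm$mz), decreasing = TRUE))
  expect_true(all(top_mz[1:2] %in% c("43", "57")))

  # feature-set mismatch is a consistency error; empty selection is allowed
  fm_sub <- fm
  fm_sub$values <- fm_sub$values[, -1]
  fm_sub$features <- fm_sub$features[-1]
  expect_error(export_marker_map(fm_sub, sr),
               class = "breathmark_consistency_error")
  sr_empty <- sr
  sr_empty$selected <- sr$selected[0]
  expect_identical(nrow(export_marker_map(fm, sr_empty)), 0L)
})

test_that("preprocessing configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("segment_width_s: 5", "is_mz: 95", "reference_is_rt: 602.5",
               "min_prevalence: 0.05"), path)
  cfg <- read_preprocess_config(path)
  expect_equal(cfg$reference_is_rt, 602.5)
  expect_equal(cfg$min_prevalence, 0.05)
  writeLines(c("segment_width_s: 5", "not_a_key: 1"), path)
  expect_error(read_preprocess_config(path), class = "breathmark_format_error")
})

test_that("metadata validation enforces the cohort invariants", {
  m <- rbind(make_meta("a_A", "a", lab = "A"), make_meta("a_B", "a", lab = "B"))
  expect_silent(validate_sample_meta(m))

  bad <- rbind(m, make_meta("a_A2", "a", lab = "A"))  # 2 lab-A samples, one subject
  expect_error(validate_sample_meta(bad), class = "breathmark_validation_error")

  bad2 <- make_meta("x", "x", group = 2L, cancer_status = "positive")
  expect_error(validate_sample_meta(bad2), class = "breathmark_validation_error")

  bad3 <- rbind(make_meta("a_A", "a", phase = "model_building"),
                make_meta("a_B", "a", lab = "B", phase = "model_testing"))
  expect_error(validate_sample_meta(bad3), class = "breathmark_validation_error")

  path <- withr::local_tempfile(fileext = ".csv")
  m$age[1] <- NA
  write_sample_meta(m, path)
  m2 <- read_sample_meta(path)
  expect_true(is.na(m2$age[1]))
  expect_identical(m2$sample_id, m$sample_id)
})

test_that("screening labels pick confirmed cancer vs CT-negative controls only", {
  meta <- rbind(make_meta("c", "c", group = 3L, cancer_status = "positive"),
                make_meta("n", "n", group = 1L, cancer_status = "negative"),
                make_meta("g2", "g2", group = 2L, cancer_status = "unknown"),
                make_meta("g4", "g4", group = 4L, cancer_status = "unknown"),
                make_meta("air", "c2", group = 3L, cancer_status = "positive",
                          sample_kind = "room_air"))
  y <- screening_labels(meta)
  expect_identical(y, c(TRUE, FALSE, NA, NA, NA))
})
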