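#' Configuration for the synthetic breath cohort generator
#'
#' The generator emulates the statistical structure of a two-phase,
#' two-laboratory breath-VOC study: a large field of null mass ions, a
#' minority of informative ions with modest effect sizes, and duplicate
#' samples per subject assayed at two laboratories with correlated
#' intensities. Intensities follow a log-normal model: each subject has a
#' latent log-intensity per ion (between-subject SD `log_sd_subject`); each
#' laboratory's measurement adds independent log-scale noise
#' (`log_sd_lab`); a per-sample loading factor (SD `loading_sd`) multiplies
#' every record including the internal standard, and is therefore removed
#' exactly by internal-standard normalization.
#'
#' Informative ions receive a log-mean shift of `+/- delta` in cancer
#' subjects, with `delta = sqrt(2) * sigma * qnorm(target_auc)` where
#' `sigma^2 = log_sd_subject^2 + log_sd_lab^2` is the per-measurement
#' log-scale variance. Under this calibration the per-laboratory
#' intensity of an informative ion has theoretical two-class AUC exactly
#' `target_auc`, which serves as a closed-form oracle in tests. The default
#' `log_sd_lab` makes the between-laboratory correlation of per-ion log
#' intensities `log_sd_subject^2 / (log_sd_subject^2 + log_sd_lab^2)` equal
#' to 0.88, the replicate concordance observed in the study this design
#' emulates.
#'
#' Defaults mirror the study conditions: 95 cancer / 81 control subjects in
#' the model-building phase, 700 segments x 100 ions = 70,000 candidate mass
#' ions, 544 informative ions at modest effect size (AUC 0.70).
#'
#' @param n_cancer,n_control Subjects per class.
#' @param n_segments Number of 5-second retention-time segments.
#' @param ions_per_segment Mass ions per segment.
#' @param n_informative Number of informative (class-shifted) ions.
#' @param target_auc Theoretical per-ion AUC of informative ions, in
#'   (0.5, 1).
#' @param log_sd_subject Between-subject log-intensity SD.
#' @param log_sd_lab Within-subject between-laboratory log-intensity SD.
#' @param baseline_log_mean Log-scale mean intensity of null ions.
#' @param is_intensity Raw abundance of the internal-standard record.
#' @param loading_sd Log-scale SD of the per-sample loading factor applied
#'   to all records (including the internal standard).
#' @param lab_bias Log-scale systematic offset between laboratories
#'   (+bias/2 at A, -bias/2 at B); default 0. Nonzero values stress-test
#'   normalization and concordance.
#' @param informative_mz Optional integer vector of m/z values to assign to
#'   informative ions (e.g. `c(43, 57)` for an alkane-fragment-like truth);
#'   `NULL` keeps the generic m/z layout.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cancer = 95, n_control = 81, n_segments = 700,
                       ions_per_segment = 100, n_informative = 544,
                       target_auc = 0.70, log_sd_subject = 0.75,
                       log_sd_lab = log_sd_subject * sqrt(1 / 0.88 - 1),
                       baseline_log_mean = 11.5, is_intensity = 1e6,
                       loading_sd = 0.2, lab_bias = 0,
                       informative_mz = NULL, seed = 1L) {
  ok <- is.numeric(n_cancer) && n_cancer >= 1 &&
    is.numeric(n_control) && n_control >= 1 &&
    is.numeric(n_segments) && n_segments >= 1 &&
    is.numeric(ions_per_segment) && ions_per_segment >= 1 &&
    is.numeric(n_informative) && n_informative >= 0 &&
    n_informative <= n_segments * ions_per_segment &&
    is.numeric(target_auc) && target_auc > 0.5 && target_auc < 1 &&
    is.numeric(log_sd_subject) && log_sd_subject > 0 &&
    is.numeric(log_sd_lab) && log_sd_lab > 0 &&
    is.numeric(is_intensity) && is_intensity > 0 &&
    is.numeric(loading_sd) && loading_sd >= 0 &&
    is.numeric(seed) && abs(seed) < 2^31
  if (!ok) bm_stop("invalid simulation configuration", "breathmark_validation_error")
  if (!is.null(informative_mz)) {
    informative_mz <- as.integer(informative_mz)
    if (any(informative_mz < 1) || anyDuplicated(informative_mz) ||
        95L %in% informative_mz) {
      bm_stop("informative_mz must be unique masses >= 1, excluding 95",
              "breathmark_validation_error")
    }
  }
  structure(list(n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
                 n_segments = as.integer(n_segments),
                 ions_per_segment = as.integer(ions_per_segment),
                 n_informative = as.integer(n_informative),
                 target_auc = target_auc, log_sd_subject = log_sd_subject,
                 log_sd_lab = log_sd_lab, baseline_log_mean = baseline_log_mean,
                 is_intensity = is_intensity, loading_sd = loading_sd,
                 lab_bias = lab_bias, informative_mz = informative_mz,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic ion map shared by both study phases: segment k gets the same
# ions_per_segment masses (a fixed pool excluding m/z 95 and any reserved
# informative masses). Retention times sit at segment midpoints: the
# generator emulates *aligned* chromatograms, where upstream software has
# already placed each compound at a consensus retention time.
build_ion_map <- function(config) {
  pool <- setdiff(30:300, c(95L, config$informative_mz))
  if (length(pool) < config$ions_per_segment) {
    bm_stop("ions_per_segment too large for the m/z pool", "breathmark_validation_error")
  }
  mzs <- pool[seq_len(config$ions_per_segment)]
  map <- data.table(
    segment = rep(seq_len(config$n_segments) - 1L, each = config$ions_per_segment),
    mz = rep(as.integer(mzs), config$n_segments)
  )
  map[, rt := segment * 5 + 2.5]
  map[]
}

# retention time of the internal-standard record (segment 120)
IS_RT <- 602.5

#' Simulate a model-building cohort with known ground truth
#'
#' Draws subjects, latent per-ion log intensities, and two laboratories'
#' ion tables per subject (see [sim_config()] for the intensity model), and
#' returns the generator's ground truth: which (segment, m/z) features are
#' informative, their direction (+1 elevated in cancer, -1 depressed), and
#' their theoretical per-ion AUC. Identical configuration (including seed)
#' gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @param phase Study phase label for the metadata
#'   (default `"model_building"`).
#' @param subject_prefix Prefix for generated subject ids.
#' @return An object of class `breath_cohort`: list with `meta` (one row per
#'   sample, two samples per subject), `tables_a`, `tables_b` (lists of
#'   `ion_table`), `truth` (class `breath_truth`), and `config`.
#' @export
simulate_cohort <- function(config, phase = "model_building",
                            subject_prefix = "S") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    truth <- draw_truth(config)
    cohort <- draw_samples(config, truth, phase, subject_prefix)
  })
  cohort
}

#' Simulate an independent blinded cohort from an existing ground truth
#'
#' New subjects are drawn from the same distributions — same informative
#' features, directions, and effect sizes — as the cohort that produced
#' `truth`, with metadata phase `model_testing`. Use a `config` with the
#' blinded-phase class sizes (the study's were 73 cancer / 68 control) and a
#' different seed.
#'
#' @param config A [sim_config()] whose dimensions match `truth`.
#' @param truth A `breath_truth` from a prior [simulate_cohort()] call.
#' @param subject_prefix Prefix for generated subject ids (default `"T"`,
#'   keeping blinded subject ids disjoint from the building phase).
#' @return A `breath_cohort` (see [simulate_cohort()]).
#' @export
simulate_blinded_cohort <- function(config, truth, subject_prefix = "T") {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "breath_truth"))
  if (config$n_segments != truth$dims$n_segments ||
      config$ions_per_segment != truth$dims$ions_per_segment) {
    bm_stop("config dimensions do not match ground truth",
            "breathmark_consistency_error")
  }
  with_seed(config$seed, {
    cohort <- draw_samples(config, truth, "model_testing", subject_prefix)
  })
  cohort
}

draw_truth <- function(config) {
  map <- build_ion_map(config)
  p <- nrow(map)
  sigma_meas <- sqrt(config$log_sd_subject^2 + config$log_sd_lab^2)
  delta <- sqrt(2) * sigma_meas * qnorm(config$target_auc)
  idx <- integer(0)
  direction <- integer(0)
  if (config$n_informative > 0) {
    idx <- sort(sample.int(p, config$n_informative))
    direction <- sample(c(-1L, 1L), config$n_informative, replace = TRUE)
    if (!is.null(config$informative_mz)) {
      # give informative ions the reserved masses, distinct within a segment
      seg <- map$segment[idx]
      for (s in unique(seg)) {
        in_seg <- which(seg == s)
        if (length(in_seg) > length(config$informative_mz)) {
          bm_stop("more informative ions in a segment than informative_mz values",
                  "breathmark_validation_error")
        }
        map$mz[idx[in_seg]] <- config$informative_mz[seq_along(in_seg)]
      }
    }
  }
  informative <- map[idx, .(segment, mz)]
  informative[, `:=`(key = feature_key(segment, mz), direction = direction,
                     delta = delta, theoretical_auc = config$target_auc)]
  structure(list(map = map, informative = informative[, .(key, segment, mz,
                                                          direction, delta,
                                                          theoretical_auc)],
                 informative_index = idx, delta = delta,
                 sigma_measurement = sigma_meas,
                 dims = list(n_segments = config$n_segments,
                             ions_per_segment = config$ions_per_segment)),
            class = "breath_truth")
}

#' @export
print.breath_truth <- function(x, ...) {
  cat(sprintf("<breath_truth> %d ions, %d informative (delta %.3f, theoretical AUC %.3f)\n",
              nrow(x$map), nrow(x$informative), x$delta,
              if (nrow(x$informative)) x$informative$theoretical_auc[1] else NA))
  invisible(x)
}

site_pool <- c("site_DE", "site_NYP", "site_NYU", "site_FL", "site_WA")

draw_samples <- function(config, truth, phase, subject_prefix) {
  n <- config$n_cancer + config$n_control
  p <- nrow(truth$map)
  subject_id <- sprintf("%s%04d", subject_prefix, seq_len(n))
  cancer <- rep(c(TRUE, FALSE), c(config$n_cancer, config$n_control))

  latent <- matrix(rnorm(n * p, 0, config$log_sd_subject), n, p) +
    config$baseline_log_mean
  if (length(truth$informative_index)) {
    shift <- truth$informative$direction * truth$delta
    latent[cancer, truth$informative_index] <-
      latent[cancer, truth$informative_index, drop = FALSE] +
      rep(shift, each = sum(cancer))
  }

  # demographics loosely matching the study's Table-1 profile
  age <- ifelse(cancer, rnorm(n, 67.7, 10.7), rnorm(n, 61.8, 7.2))
  pack_years <- pmax(0, ifelse(cancer, rnorm(n, 48.5, 28), rnorm(n, 42.1, 16.9)))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  site <- sample(site_pool, n, replace = TRUE)

  meta_subject <- data.table(
    subject_id = subject_id,
    group = ifelse(cancer, 3L, 1L),
    cancer_status = ifelse(cancer, "positive", "negative"),
    site = site, phase = phase, sample_kind = "breath",
    age = round(age, 1), pack_years = round(pack_years, 1), sex = sex
  )

  make_lab <- function(lab) {
    bias <- if (lab == "A") config$lab_bias / 2 else -config$lab_bias / 2
    meas <- latent + matrix(rnorm(n * p, 0, config$log_sd_lab), n, p) + bias
    loading <- rnorm(n, 0, config$loading_sd)
    meas <- meas + loading          # recycles by row: one factor per sample
    intensity <- exp(meas)
    is_int <- config$is_intensity * exp(loading)
    ids <- paste0(subject_id, "_", lab)
    tables <- lapply(seq_len(n), function(i) {
      rec <- data.table(rt = c(truth$map$rt, IS_RT),
                        mz = c(truth$map$mz, 95L),
                        intensity = c(intensity[i, ], is_int[i]))
      ion_table(ids[i], rec)
    })
    list(ids = ids, tables = tables)
  }
  lab_a <- make_lab("A")
  lab_b <- make_lab("B")

  meta <- rbindlist(list(
    data.table(sample_id = lab_a$ids, meta_subject, lab = "A"),
    data.table(sample_id = lab_b$ids, meta_subject, lab = "B")
  ))
  setcolorder(meta, meta_columns)
  meta <- validate_sample_meta(meta)

  structure(list(meta = meta, tables_a = lab_a$tables, tables_b = lab_b$tables,
                 truth = truth, config = config),
            class = "breath_cohort")
}

#' @export
print.breath_cohort <- function(x, ...) {
  cat(sprintf("<breath_cohort> %d subjects (%d cancer / %d control), %d ions, phase %s\n",
              x$config$n_cancer + x$config$n_control, x$config$n_cancer,
              x$config$n_control, nrow(x$truth$map), x$meta$phase[1]))
  invisible(x)
}

#' Normalize and bin a simulated cohort into a feature matrix
#'
#' Convenience wrapper: normalizes every ion table of the requested
#' laboratories to the internal standard and bins the pooled tables (each
#' laboratory's sample is a separate row, as when duplicate assays from two
#' laboratories are pooled for analysis).
#'
#' @param cohort A `breath_cohort`.
#' @param labs Laboratories to include (default both).
#' @param config A [preprocess_config()].
#' @return A `feature_matrix`.
#' @export
cohort_feature_matrix <- function(cohort, labs = c("A", "B"),
                                  config = preprocess_config()) {
  stopifnot(inherits(cohort, "breath_cohort"))
  tabs <- c(if ("A" %in% labs) cohort$tables_a,
            if ("B" %in% labs) cohort$tables_b)
  tabs <- lapply(tabs, normalize_table, config = config)
  bin_to_features(tabs, cohort$meta, config)
}

#' Write a simulated cohort to disk as CSV files
#'
#' Writes one pooled ion-table CSV per laboratory, the metadata CSV, and the
#' ground-truth CSV (feature key, direction, theoretical AUC).
#'
#' @param cohort A `breath_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "breath_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- function(tabs) {
    rbindlist(lapply(tabs, function(t) data.table(sample_id = t$sample_id, t$records)))
  }
  fwrite(pool(cohort$tables_a), file.path(dir, "ion_tables_lab_A.csv"))
  fwrite(pool(cohort$tables_b), file.path(dir, "ion_tables_lab_B.csv"))
  write_sample_meta(cohort$meta, file.path(dir, "sample_meta.csv"))
  fwrite(cohort$truth$informative, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
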