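#' Preprocessing configuration for aligned ion tables
#'
#' Bundles the parameters of the preprocessing step: the retention-time
#' segment width used for binning, the unit mass of the internal-standard
#' ion (bromofluorobenzene fragments at m/z 95), an optional reference
#' retention time for the internal standard (used to rescale retention times
#' so the standard elutes at the same time in every chromatogram), the
#' retention-time window searched for the internal-standard record, and a
#' minimum-prevalence filter for features.
#'
#' @param segment_width_s Width of a retention-time segment in seconds
#'   (default 5, the binning resolution of the pipeline).
#' @param is_mz Unit mass of the internal-standard ion (default 95).
#' @param reference_is_rt Reference retention time (seconds) of the internal
#'   standard. If `NULL` (default) retention times are left on their observed
#'   scale; otherwise every record's retention time is multiplied by
#'   `reference_is_rt / observed_is_rt` during normalization.
#' @param min_prevalence Features present (non-zero) in fewer than this
#'   fraction of samples are dropped when binning (default 0: keep all).
#' @param is_rt_window Length-2 numeric, the retention-time window (seconds)
#'   searched for the internal-standard record (default the whole run).
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(segment_width_s = 5, is_mz = 95L,
                              reference_is_rt = NULL, min_prevalence = 0,
                              is_rt_window = c(0, Inf)) {
  stopifnot(
    is.numeric(segment_width_s), length(segment_width_s) == 1, segment_width_s > 0,
    is.numeric(is_mz), length(is_mz) == 1, is_mz >= 1,
    is.numeric(min_prevalence), min_prevalence >= 0, min_prevalence <= 1,
    is.numeric(is_rt_window), length(is_rt_window) == 2,
    is_rt_window[1] <= is_rt_window[2]
  )
  if (!is.null(reference_is_rt)) {
    stopifnot(is.numeric(reference_is_rt), length(reference_is_rt) == 1,
              reference_is_rt > 0)
  }
  structure(
    list(segment_width_s = segment_width_s, is_mz = as.integer(round_half_up(is_mz)),
         reference_is_rt = reference_is_rt, min_prevalence = min_prevalence,
         is_rt_window = as.numeric(is_rt_window)),
    class = "preprocess_config"
  )
}

#' Read a preprocessing configuration from a YAML file
#'
#' Recognised keys: `segment_width_s`, `is_mz`, `reference_is_rt`,
#' `min_prevalence`, `is_rt_window`. Missing keys take the
#' [preprocess_config()] defaults; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `preprocess_config` object.
#' @export
read_preprocess_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(preprocess_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    bm_stop(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
            "breathmark_format_error")
  }
  do.call(preprocess_config, y)
}

#' Construct a validated ion table for one breath sample
#'
#' An ion table is the long-form output of chromatogram alignment for one
#' sample: one record per detected (retention time, m/z) mass ion with its
#' intensity. Fractional m/z values are rounded half-up to unit mass. The
#' internal-standard record is located as the maximum-intensity record at
#' `config$is_mz` within `config$is_rt_window`; a table without one is
#' rejected, because intensity normalization is anchored on it.
#'
#' @param sample_id Sample identifier (scalar character).
#' @param records A data frame with columns `rt` (seconds), `mz`, `intensity`.
#' @param config A [preprocess_config()].
#' @return An object of class `ion_table` with fields `sample_id`, `records`
#'   (a `data.table` with integer `mz`), and `is_index` (row index of the
#'   internal-standard record).
#' @export
ion_table <- function(sample_id, records, config = preprocess_config()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1, nzchar(sample_id))
  need <- c("rt", "mz", "intensity")
  if (!all(need %in% names(records))) {
    bm_stop(paste0("ion records need columns: ", paste(need, collapse = ", ")),
            "breathmark_format_error")
  }
  rec <- as.data.table(records)[, .(rt = as.numeric(rt),
                                    mz = as.integer(round_half_up(as.numeric(mz))),
                                    intensity = as.numeric(intensity))]
  if (nrow(rec) == 0) bm_stop("empty ion table", "breathmark_validation_error")
  if (anyNA(rec)) bm_stop("NA in ion records", "breathmark_validation_error")
  if (any(rec$rt < 0)) bm_stop("negative retention time", "breathmark_validation_error")
  if (any(rec$mz < 1)) bm_stop("m/z below 1", "breathmark_validation_error")
  if (any(rec$intensity < 0)) {
    bm_stop("negative intensity", "breathmark_validation_error")
  }
  cand <- which(rec$mz == config$is_mz &
                  rec$rt >= config$is_rt_window[1] &
                  rec$rt <= config$is_rt_window[2])
  if (!length(cand)) {
    bm_stop(sprintf("sample '%s': no internal-standard record (m/z %d) in window",
                    sample_id, config$is_mz),
            "breathmark_missing_internal_standard")
  }
  is_index <- cand[which.max(rec$intensity[cand])]
  if (rec$intensity[is_index] <= 0) {
    bm_stop(sprintf("sample '%s': internal-standard intensity is zero", sample_id),
            "breathmark_missing_internal_standard")
  }
  structure(list(sample_id = sample_id, records = rec, is_index = is_index),
            class = "ion_table")
}

#' @export
print.ion_table <- function(x, ...) {
  cat(sprintf("<ion_table> sample '%s': %d records, IS intensity %.6g at rt %.1f s%s\n",
              x$sample_id, nrow(x$records),
              x$records$intensity[x$is_index], x$records$rt[x$is_index],
              if (is_normalized(x)) " (normalized)" else ""))
  invisible(x)
}

#' Test whether an ion table has been intensity-normalized
#'
#' A table counts as normalized when its internal-standard intensity equals 1
#' (the invariant [normalize_table()] establishes).
#'
#' @param t An `ion_table`.
#' @return Logical scalar.
#' @export
is_normalized <- function(t) {
  stopifnot(inherits(t, "ion_table"))
  isTRUE(all.equal(t$records$intensity[t$is_index], 1))
}

#' Read one sample's ion table from a delimited file
#'
#' The file must be a long-form delimited table with header columns
#' `sample_id`, `rt`, `mz`, `intensity` and exactly one distinct sample id
#' (use [read_ion_tables()] for pooled files).
#'
#' @param path Path to a CSV/TSV file.
#' @param config A [preprocess_config()].
#' @return An `ion_table`.
#' @export
read_ion_table <- function(path, config = preprocess_config()) {
  dt <- fread(path)
  need <- c("sample_id", "rt", "mz", "intensity")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    bm_stop(paste0("missing columns: ", paste(miss, collapse = ", ")),
            "breathmark_format_error")
  }
  ids <- unique(dt$sample_id)
  if (length(ids) != 1) {
    bm_stop("file contains multiple sample_ids; use read_ion_tables()",
            "breathmark_format_error")
  }
  ion_table(as.character(ids), dt[, .(rt, mz, intensity)], config)
}

#' Read a pooled ion-table file or a directory of per-sample files
#'
#' @param path A directory containing `*.csv` files (one sample each) or a
#'   single pooled file with several `sample_id` values.
#' @param config A [preprocess_config()].
#' @return A named list of `ion_table` objects.
#' @export
read_ion_tables <- function(path, config = preprocess_config()) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    if (!length(files)) bm_stop("no ion-table files in directory", "breathmark_format_error")
    tabs <- lapply(files, read_ion_table, config = config)
  } else {
    dt <- fread(path)
    need <- c("sample_id", "rt", "mz", "intensity")
    miss <- setdiff(need, names(dt))
    if (length(miss)) {
      bm_stop(paste0("missing columns: ", paste(miss, collapse = ", ")),
              "breathmark_format_error")
    }
    tabs <- lapply(split(dt, by = "sample_id"), function(d) {
      ion_table(as.character(d$sample_id[1]), d[, .(rt, mz, intensity)], config)
    })
  }
  setNames(tabs, vapply(tabs, `[[`, "", "sample_id"))
}

#' Write an ion table to CSV
#'
#' Values are written with shortest round-trip representation, so
#' write-then-read reproduces the table exactly.
#'
#' @param t An `ion_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(t, path) {
  stopifnot(inherits(t, "ion_table"))
  fwrite_exact(data.table(sample_id = t$sample_id, t$records), path)
  invisible(path)
}

#' Normalize an ion table to its internal standard
#'
#' Every intensity is divided by the internal-standard intensity (so the
#' standard itself becomes 1 and all other values are dimensionless ratios).
#' If `config$reference_is_rt` is set, every retention time is multiplied by
#' `reference_is_rt / observed_is_rt`, a single-point linear rescaling that
#' places the internal standard at the same retention time in every
#' chromatogram. Applying the function to an already-normalized table is a
#' no-op.
#'
#' @param t An `ion_table`.
#' @param config A [preprocess_config()].
#' @return A normalized `ion_table`.
#' @export
normalize_table <- function(t, config = preprocess_config()) {
  stopifnot(inherits(t, "ion_table"))
  is_int <- t$records$intensity[t$is_index]
  if (is_int == 0) {
    bm_stop(sprintf("sample '%s': internal-standard intensity 0, cannot normalize",
                    t$sample_id), "breathmark_division_error")
  }
  rec <- copy(t$records)
  rec[, intensity := intensity / is_int]
  if (!is.null(config$reference_is_rt)) {
    obs_rt <- rec$rt[t$is_index]
    if (obs_rt <= 0) {
      bm_stop("internal-standard retention time must be positive to rescale",
              "breathmark_division_error")
    }
    rec[, rt := rt * (config$reference_is_rt / obs_rt)]
  }
  structure(list(sample_id = t$sample_id, records = rec, is_index = t$is_index),
            class = "ion_table")
}

feature_key <- function(segment, mz) sprintf("seg%d_mz%d", segment, mz)

parse_feature_keys <- function(keys) {
  m <- regmatches(keys, regexec("^seg([0-9]+)_mz([0-9]+)$", keys))
  bad <- lengths(m) != 3
  if (any(bad)) {
    bm_stop(paste0("unparseable feature keys: ",
                   paste(head(keys[bad], 3), collapse = ", ")),
            "breathmark_format_error")
  }
  out <- data.table(segment = as.integer(vapply(m, `[[`, "", 2)),
                    mz = as.integer(vapply(m, `[[`, "", 3)))
  out[, key := keys]
  setcolorder(out, c("key", "segment", "mz"))
  out[]
}

#' Bin normalized ion tables into a feature matrix
#'
#' Each record is assigned to the half-open retention-time segment
#' `[w*k, w*(k+1))` with `k = floor(rt / w)` (`w` = `config$segment_width_s`).
#' Records falling in the same (sample, segment, m/z) cell are summed (ion
#' current is additive); a feature absent from a sample's table is 0, i.e.
#' absence of signal rather than missingness. All tables must already be
#' intensity-normalized.
#'
#' @param tables A list of normalized `ion_table` objects.
#' @param meta A sample-metadata data frame covering every `sample_id`
#'   (see [read_sample_meta()]).
#' @param config A [preprocess_config()].
#' @return An object of class `feature_matrix`: a list with `values` (a
#'   samples x features numeric matrix, rownames = sample ids, colnames =
#'   `seg<k>_mz<m>`), `features` (a `data.table` with `key`, `segment`, `mz`),
#'   and `meta` (rows aligned with the matrix).
#' @export
bin_to_features <- function(tables, meta, config = preprocess_config()) {
  stopifnot(is.list(tables), length(tables) > 0)
  ids <- vapply(tables, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) bm_stop("duplicate sample_ids", "breathmark_validation_error")
  meta <- as.data.table(meta)
  if (!"sample_id" %in% names(meta)) {
    bm_stop("metadata lacks sample_id column", "breathmark_format_error")
  }
  missing_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_meta)) {
    bm_stop(paste0("metadata missing for samples: ",
                   paste(head(missing_meta, 3), collapse = ", ")),
            "breathmark_meta_error")
  }
  for (t in tables) {
    if (!is_normalized(t)) {
      bm_stop(sprintf("sample '%s' is not normalized (IS intensity != 1)",
                      t$sample_id), "breathmark_state_error")
    }
  }
  w <- config$segment_width_s
  long <- rbindlist(lapply(tables, function(t) {
    data.table(sample_id = t$sample_id,
               segment = as.integer(floor(t$records$rt / w)),
               mz = t$records$mz,
               value = t$records$intensity)
  }))
  agg <- long[, .(value = sum(value)), by = .(sample_id, segment, mz)]
  feats <- unique(agg[, .(segment, mz)])
  setorder(feats, segment, mz)
  feats[, key := feature_key(segment, mz)]
  agg[, key := feature_key(segment, mz)]
  values <- matrix(0, nrow = length(ids), ncol = nrow(feats),
                   dimnames = list(ids, feats$key))
  values[cbind(match(agg$sample_id, ids), match(agg$key, feats$key))] <- agg$value
  if (config$min_prevalence > 0) {
    keep <- colMeans(values > 0) >= config$min_prevalence
    values <- values[, keep, drop = FALSE]
    feats <- feats[keep]
  }
  meta_aligned <- meta[match(ids, meta$sample_id)]
  structure(list(values = values, features = feats[, .(key, segment, mz)],
                 meta = meta_aligned),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (segments %d-%d)\n",
              nrow(x$values), ncol(x$values),
              min(x$features$segment), max(x$features$segment)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by sample
#'
#' @param fm A `feature_matrix`.
#' @param idx Logical or integer index over samples (rows).
#' @return A `feature_matrix` restricted to the selected samples.
#' @export
subset_feature_matrix <- function(fm, idx) {
  stopifnot(inherits(fm, "feature_matrix"))
  structure(list(values = fm$values[idx, , drop = FALSE],
                 features = fm$features,
                 meta = fm$meta[idx]),
            class = "feature_matrix")
}

#' Write a feature matrix to CSV
#'
#' First column `sample_id`, remaining columns named `seg<k>_mz<m>`.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  dt <- data.table(sample_id = rownames(fm$values))
  dt <- cbind(dt, as.data.table(fm$values))
  fwrite_exact(dt, path)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path Path to a CSV written by [write_feature_matrix()].
#' @param meta Optional sample metadata to attach (matched on `sample_id`).
#' @return A `feature_matrix` (with `meta = NULL` if none supplied).
#' @export
read_feature_matrix <- function(path, meta = NULL) {
  dt <- fread(path)
  if (names(dt)[1] != "sample_id") {
    bm_stop("first column must be sample_id", "breathmark_format_error")
  }
  feats <- parse_feature_keys(names(dt)[-1])
  values <- as.matrix(dt[, -1])
  rownames(values) <- as.character(dt$sample_id)
  if (any(values < 0)) bm_stop("negative feature values", "breathmark_validation_error")
  meta_aligned <- NULL
  if (!is.null(meta)) {
    meta <- as.data.table(meta)
    meta_aligned <- meta[match(rownames(values), meta$sample_id)]
    if (anyNA(meta_aligned$sample_id)) {
      bm_stop("metadata missing for some samples", "breathmark_meta_error")
    }
  }
  structure(list(values = values, features = feats, meta = meta_aligned),
            class = "feature_matrix")
}

#' Export selected markers as a retention-time / m/z map
#'
#' Produces one row per selected feature with the retention-time midpoint of
#' its segment, its unit mass, and its C-statistic — the table behind the
#' classic marker-map scatter (m/z against retention time), where vertical
#' clusters suggest fragments of a single parent VOC and horizontal clusters
#' at m/z 43/57 suggest alkane-type fragments. No plotting is performed.
#'
#' @param fm The `feature_matrix` the screen was computed on.
#' @param result A `screen_result` from [screen_markers()].
#' @param config The [preprocess_config()] used for binning (supplies the
#'   segment width).
#' @return A `data.table` with columns `rt_mid` (seconds), `mz`,
#'   `c_statistic`.
#' @export
export_marker_map <- function(fm, result, config = preprocess_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(result, "screen_result"))
  if (!identical(sort(result$scores$features$key), sort(fm$features$key))) {
    bm_stop("screen result was not computed on this feature matrix",
            "breathmark_consistency_error")
  }
  sel <- result$selected
  w <- config$segment_width_s
  data.table(rt_mid = sel$segment * w + w / 2,
             mz = sel$mz,
             c_statistic = sel$c_correct)
}
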