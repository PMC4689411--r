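meta_columns <- c("sample_id", "subject_id", "group", "cancer_status", "lab",
                  "site", "phase", "sample_kind", "age", "pack_years", "sex")

#' Validate a sample-metadata table
#'
#' Enforces the cohort bookkeeping invariants: unique sample ids; group in
#' 1-4 (1 = asymptomatic high-risk smokers with screening chest CT, 2 =
#' symptomatic without tissue diagnosis, 3 = symptomatic with tissue
#' diagnosis, 4 = healthy); a tissue-positive cancer status only in groups 1
#' or 3; at most one sample per subject per laboratory per sample kind; and
#' disjoint phase membership (no subject in both the model-building and
#' model-testing phase).
#'
#' @param meta A data frame with columns `sample_id`, `subject_id`, `group`,
#'   `cancer_status` (positive/negative/unknown), `lab` (A/B), `site`,
#'   `phase` (model_building/model_testing), `sample_kind` (breath/room_air),
#'   `age`, `pack_years`, `sex` (M/F, may be missing).
#' @return The validated metadata as a `data.table`, invisibly usable
#'   downstream.
#' @export
validate_sample_meta <- function(meta) {
  meta <- as.data.table(meta)
  miss <- setdiff(meta_columns, names(meta))
  if (length(miss)) {
    bm_stop(paste0("metadata missing columns: ", paste(miss, collapse = ", ")),
            "breathmark_format_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    bm_stop("duplicate sample_id in metadata", "breathmark_validation_error")
  }
  if (!all(meta$group %in% 1:4)) {
    bm_stop("group must be 1, 2, 3 or 4", "breathmark_validation_error")
  }
  if (!all(meta$cancer_status %in% c("positive", "negative", "unknown"))) {
    bm_stop("cancer_status must be positive/negative/unknown",
            "breathmark_validation_error")
  }
  if (!all(meta$lab %in% c("A", "B"))) {
    bm_stop("lab must be A or B", "breathmark_validation_error")
  }
  if (!all(meta$phase %in% c("model_building", "model_testing"))) {
    bm_stop("phase must be model_building or model_testing",
            "breathmark_validation_error")
  }
  if (!all(meta$sample_kind %in% c("breath", "room_air"))) {
    bm_stop("sample_kind must be breath or room_air", "breathmark_validation_error")
  }
  if (!all(meta$sex %in% c("M", "F") | is.na(meta$sex))) {
    bm_stop("sex must be M, F or missing", "breathmark_validation_error")
  }
  if (any(meta$cancer_status == "positive" & !(meta$group %in% c(1, 3)))) {
    bm_stop("cancer_status 'positive' only allowed in groups 1 or 3",
            "breathmark_validation_error")
  }
  if (any(!is.na(meta$age) & meta$age < 0) ||
      any(!is.na(meta$pack_years) & meta$pack_years < 0)) {
    bm_stop("age and pack_years must be nonnegative", "breathmark_validation_error")
  }
  dup <- meta[, .N, by = .(subject_id, lab, sample_kind)][N > 1]
  if (nrow(dup)) {
    bm_stop("a subject has more than one sample for the same lab and sample kind",
            "breathmark_validation_error")
  }
  ph <- meta[, .(n_phase = uniqueN(phase)), by = subject_id][n_phase > 1]
  if (nrow(ph)) {
    bm_stop("a subject appears in both study phases", "breathmark_validation_error")
  }
  meta[]
}

#' Read sample metadata from CSV
#'
#' Empty strings are treated as missing. The table is validated with
#' [validate_sample_meta()].
#'
#' @param path Path to a metadata CSV.
#' @return A validated `data.table` of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- fread(path, colClasses = list(character = c("sample_id", "subject_id",
                                                      "site", "sex")),
                na.strings = c("", "NA"))
  meta[, `:=`(age = as.numeric(age), pack_years = as.numeric(pack_years))]
  validate_sample_meta(meta)
}

#' Write sample metadata to CSV
#'
#' @param meta A metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  fwrite(as.data.table(meta), path)
  invisible(path)
}

#' Screening labels: tissue-confirmed cancer vs CT-negative controls
#'
#' The biomarker screen compares group 3 subjects with a tissue-confirmed
#' cancer (label `TRUE`) against group 1 subjects with a negative screening
#' chest CT (label `FALSE`). Every other sample — groups 2 and 4, unknown
#' status, room-air samples — gets `NA` and is excluded from screening and
#' model fitting (it still receives a discriminant-function value at
#' prediction time).
#'
#' @param meta A sample-metadata table.
#' @return A logical vector aligned with the rows of `meta`.
#' @export
screening_labels <- function(meta) {
  meta <- as.data.table(meta)
  y <- rep(NA, nrow(meta))
  y[meta$group == 3 & meta$cancer_status == "positive" &
      meta$sample_kind == "breath"] <- TRUE
  y[meta$group == 1 & meta$cancer_status == "negative" &
      meta$sample_kind == "breath"] <- FALSE
  y
}
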