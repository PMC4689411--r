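#' Sensitivity/specificity curves over DF cutoffs, crossover, and ROC AUC
#'
#' Evaluates the binary test "DF strictly greater than cutoff is positive"
#' at every distinct observed DF value plus 0. Sensitivity is non-increasing
#' and specificity non-decreasing in the cutoff; at cutoff 0 every sample
#' with any firing rule is positive. The discrete sensitivity and
#' specificity step curves rarely intersect exactly, so the crossover
#' operating point is taken as the cutoff maximizing sensitivity +
#' specificity (the quantity that is maximal where the continuous curves
#' intersect), ties toward the smaller cutoff. The AUC is the Mann-Whitney
#' C-statistic of DF for cancer vs cancer-free.
#'
#' @param dfs Numeric DF values, or the `data.frame` from [predict_df()].
#' @param labels Binary labels (`TRUE` = cancer); `NA` (unknown status)
#'   pairs are excluded.
#' @return An object of class `perf_curve`: list with `cutoffs`, `sens`,
#'   `spec`, confusion `counts` (tp/fn/tn/fp per cutoff), `crossover`
#'   (df/sens/spec), `auc`, `n_cancer`, `n_control`.
#' @export
perf_curve <- function(dfs, labels) {
  if (is.data.frame(dfs)) dfs <- dfs$df
  labels <- as_binary_labels(labels)
  stopifnot(length(dfs) == length(labels))
  keep <- !is.na(labels) & !is.na(dfs)
  dfs <- dfs[keep]
  labels <- labels[keep]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    bm_stop("both classes must be present", "breathmark_degenerate_error")
  }
  cutoffs <- sort(unique(c(0, dfs)))
  tp <- vapply(cutoffs, function(cc) sum(dfs[labels] > cc), numeric(1))
  fp <- vapply(cutoffs, function(cc) sum(dfs[!labels] > cc), numeric(1))
  fn <- n1 - tp
  tn <- n0 - fp
  sens <- tp / n1
  spec <- tn / n0
  cross <- which.max(sens + spec)        # first maximum = smallest cutoff
  auc <- cstat(dfs, labels)$c_statistic
  structure(list(cutoffs = cutoffs, sens = sens, spec = spec,
                 counts = data.table(cutoff = cutoffs, tp = tp, fn = fn,
                                     tn = tn, fp = fp),
                 crossover = list(df = cutoffs[cross], sens = sens[cross],
                                  spec = spec[cross]),
                 auc = auc, n_cancer = n1, n_control = n0),
            class = "perf_curve")
}

#' @export
print.perf_curve <- function(x, ...) {
  cat(sprintf("<perf_curve> %d/%d cancer/control, C = %.3f; crossover DF = %.2f (sens %.1f%%, spec %.1f%%)\n",
              x$n_cancer, x$n_control, x$auc, x$crossover$df,
              100 * x$crossover$sens, 100 * x$crossover$spec))
  invisible(x)
}

#' Inter-laboratory concordance of replicate DF values
#'
#' Pairs each subject's laboratory-A and laboratory-B DF values (via the
#' metadata's sample-to-subject map) and reports their Pearson correlation
#' with a Fisher-z 95% confidence interval. Subjects missing either
#' replicate are dropped and counted.
#'
#' @param dfs_a,dfs_b `data.frame`s from [predict_df()] for the two
#'   laboratories.
#' @param meta Sample metadata mapping `sample_id` to `subject_id`.
#' @return An object of class `concordance_result`: list with `pairs`
#'   (`data.table` subject_id/df_a/df_b), `r`, `ci` (length-2), `n`,
#'   `n_dropped`.
#' @export
interlab_concordance <- function(dfs_a, dfs_b, meta) {
  meta <- as.data.table(meta)
  map <- meta[, .(sample_id, subject_id)]
  a <- merge(as.data.table(dfs_a), map, by = "sample_id")[, .(subject_id, df_a = df)]
  b <- merge(as.data.table(dfs_b), map, by = "sample_id")[, .(subject_id, df_b = df)]
  pairs <- merge(a, b, by = "subject_id")
  n_dropped <- length(union(a$subject_id, b$subject_id)) - nrow(pairs)
  if (nrow(pairs) < 3) {
    bm_stop("fewer than 3 paired subjects", "breathmark_insufficient_data")
  }
  if (sd(pairs$df_a) == 0 || sd(pairs$df_b) == 0) {
    bm_stop("zero variance in one laboratory's DF values; correlation undefined",
            "breathmark_undefined_correlation")
  }
  r <- cor(pairs$df_a, pairs$df_b)
  z <- atanh(r)
  se <- 1 / sqrt(nrow(pairs) - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  structure(list(pairs = pairs, r = r, ci = ci, n = nrow(pairs),
                 n_dropped = n_dropped),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> r = %.3f (95%% CI %.3f-%.3f), n = %d pairs (%d dropped)\n",
              x$r, x$ci[1], x$ci[2], x$n, x$n_dropped))
  invisible(x)
}

#' Blinded validation report for a frozen WDA predictor
#'
#' Scores every blinded breath sample with the frozen predictor, then (and
#' only then) unblinds: per laboratory it reports the ROC C-statistic and
#' the crossover operating point (sensitivity/specificity at the cutoff
#' maximizing their sum), plus the inter-laboratory concordance of
#' replicate DF values. Samples with unknown cancer status receive DF
#' values but are excluded from the performance metrics.
#'
#' If `model_snapshot` (the `serialize()` of the predictor taken when it
#' was frozen) is supplied, the report verifies the predictor is
#' bit-identical to the frozen one before any label is read, and errors
#' otherwise — the blinding contract.
#'
#' @param predictor A `wda_predictor`.
#' @param fm_blinded A `feature_matrix` of blinded samples with metadata.
#' @param model_snapshot Optional raw vector from
#'   `serialize(predictor, NULL)` taken at freeze time.
#' @return An object of class `blinded_report`: list with `per_lab` (a
#'   `data.table`: lab, n_cancer, n_control, c_statistic, crossover_df,
#'   sensitivity, specificity), `curves` (per-lab `perf_curve`s), `dfs`
#'   (per-lab DF tables), and `concordance`.
#' @export
blinded_report <- function(predictor, fm_blinded, model_snapshot = NULL) {
  stopifnot(inherits(predictor, "wda_predictor"),
            inherits(fm_blinded, "feature_matrix"))
  if (is.null(fm_blinded$meta)) {
    bm_stop("blinded feature matrix needs metadata", "breathmark_meta_error")
  }
  if (!is.null(model_snapshot) &&
      !identical(serialize(predictor, NULL, version = 2), model_snapshot)) {
    bm_stop("predictor differs from its frozen snapshot: blinding violated",
            "breathmark_blinding_violation")
  }
  meta <- fm_blinded$meta
  labs <- sort(unique(meta$lab))
  dfs <- list()
  curves <- list()
  rows <- list()
  for (L in labs) {
    idx <- which(meta$lab == L & meta$sample_kind == "breath")
    sub <- subset_feature_matrix(fm_blinded, idx)
    d <- predict_df(predictor, sub)
    dfs[[L]] <- d
    y <- rep(NA, nrow(sub$values))
    y[sub$meta$cancer_status == "positive"] <- TRUE
    y[sub$meta$cancer_status == "negative"] <- FALSE
    pc <- perf_curve(d$df, y)
    curves[[L]] <- pc
    rows[[L]] <- data.table(lab = L, n_cancer = pc$n_cancer,
                            n_control = pc$n_control, c_statistic = pc$auc,
                            crossover_df = pc$crossover$df,
                            sensitivity = pc$crossover$sens,
                            specificity = pc$crossover$spec)
  }
  concordance <- NULL
  if (all(c("A", "B") %in% labs)) {
    concordance <- interlab_concordance(dfs[["A"]], dfs[["B"]], meta)
  }
  structure(list(per_lab = rbindlist(rows), curves = curves, dfs = dfs,
                 concordance = concordance),
            class = "blinded_report")
}

#' @export
print.blinded_report <- function(x, ...) {
  cat("<blinded_report>\n")
  for (i in seq_len(nrow(x$per_lab))) {
    r <- x$per_lab[i]
    cat(sprintf("  lab %s: %d/%d cancer/control, C = %.3f, crossover DF = %.2f (sens %.1f%%, spec %.1f%%)\n",
                r$lab, r$n_cancer, r$n_control, r$c_statistic, r$crossover_df,
                100 * r$sensitivity, 100 * r$specificity))
  }
  if (!is.null(x$concordance)) {
    cat(sprintf("  interlab concordance r = %.3f (n = %d)\n",
                x$concordance$r, x$concordance$n))
  }
  invisible(x)
}
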