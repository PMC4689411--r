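# Optimal rule threshold for one feature: the cutoff maximizing Youden's J
# (sensitivity + specificity - 1) for the rule "sign * (x - cutoff) > 0
# predicts cancer", searched over midpoints of consecutive distinct observed
# values. Ties in J break toward the smaller cutoff. A constant feature has
# no midpoints: its value is returned with J = 0 (the rule never fires).
youden_cutoff <- function(x, y, sign) {
  v <- sort(unique(x))
  if (length(v) < 2) {
    return(list(cutoff = v[1], j = 0, constant = TRUE))
  }
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  last <- cumsum(rle(xs)$lengths)        # last index of each distinct value
  c1 <- cumsum(ys)[last]                 # cancer samples with x <= v_i
  c0 <- cumsum(!ys)[last]
  n1 <- sum(y)
  n0 <- sum(!y)
  m <- length(v)
  mid <- (v[-1] + v[-m]) / 2
  i <- seq_len(m - 1)
  if (sign > 0) {                        # fires when x > cutoff
    sens <- (n1 - c1[i]) / n1
    spec <- c0[i] / n0
  } else {                               # fires when x < cutoff
    sens <- c1[i] / n1
    spec <- (n0 - c0[i]) / n0
  }
  j <- sens + spec - 1
  # first index within floating-point tolerance of the maximum = smallest cutoff
  best <- which(j >= max(j) - 1e-9)[1]
  list(cutoff = mid[best], j = j[best], constant = FALSE)
}

#' Fit a weighted digital analysis (WDA) predictor
#'
#' WDA turns each selected marker into a binary voting rule with three
#' parameters: a sign (+1 if the marker is elevated in cancer, -1 if
#' depressed — taken from the screen's orientation), a weight (the marker's
#' C-statistic), and an intensity cutoff. The cutoff is chosen to maximize
#' Youden's J for the single-marker rule, searched over midpoints of
#' consecutive distinct observed values (ties toward the smaller cutoff).
#' A sample's discriminant function (DF) is the sum of the weights of the
#' rules that fire, so DF ranges from 0 to the sum of all weights.
#'
#' @param fm The training `feature_matrix`.
#' @param labels Binary labels aligned with the rows of `fm`, or `NULL` to
#'   derive them with [screening_labels()] from `fm$meta`. `NA` rows are
#'   excluded from fitting.
#' @param selected Selected features: the `data.table` returned by
#'   [select_top_k()] (or a `screen_result`, whose selection is used).
#' @param scores The `marker_scores` the selection came from (supplies
#'   orientation and weight); defaults to `selected$scores` when `selected`
#'   is a `screen_result`.
#' @param weight_scheme `"c"` (default) uses the C-statistic as weight;
#'   `"2c-1"` uses `2C - 1` (weights in `[0, 1]`).
#' @return An object of class `wda_predictor`: list with `rules`
#'   (`data.table` key/segment/mz/cutoff/sign/weight/youden_j),
#'   `weight_scheme`, and `training_summary` (class sizes, training DF
#'   C-statistic, sensitivity/specificity at the training crossover).
#' @export
fit_wda <- function(fm, labels = NULL, selected, scores = NULL,
                    weight_scheme = c("c", "2c-1")) {
  stopifnot(inherits(fm, "feature_matrix"))
  weight_scheme <- match.arg(weight_scheme)
  if (inherits(selected, "screen_result")) {
    if (is.null(scores)) scores <- selected$scores
    selected <- selected$selected
  }
  if (is.null(scores)) {
    bm_stop("scores are required (orientation and weight come from the screen)",
            "breathmark_validation_error")
  }
  if (!nrow(selected)) {
    bm_stop("empty marker selection", "breathmark_validation_error")
  }
  if (is.null(labels)) {
    if (is.null(fm$meta)) {
      bm_stop("no labels given and feature matrix has no metadata",
              "breathmark_validation_error")
    }
    labels <- screening_labels(fm$meta)
  }
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == nrow(fm$values))
  keep <- !is.na(labels)
  X <- fm$values[keep, , drop = FALSE]
  y <- labels[keep]
  if (sum(y) == 0 || sum(!y) == 0) {
    bm_stop("both classes required to fit", "breathmark_degenerate_error")
  }
  missing_feat <- setdiff(selected$key, colnames(X))
  if (length(missing_feat)) {
    bm_stop(paste0("selected features absent from feature matrix: ",
                   paste(head(missing_feat, 3), collapse = ", ")),
            "breathmark_consistency_error")
  }
  idx <- match(selected$key, scores$features$key)
  if (anyNA(idx)) {
    bm_stop("selected features absent from scores", "breathmark_consistency_error")
  }
  sign <- scores$orientation[idx]
  cval <- scores$c_correct[idx]
  weight <- if (weight_scheme == "c") cval else 2 * cval - 1

  fits <- lapply(seq_len(nrow(selected)), function(i) {
    youden_cutoff(X[, selected$key[i]], y, sign[i])
  })
  constant <- vapply(fits, `[[`, TRUE, "constant")
  if (any(constant)) {
    warning(sprintf("%d selected feature(s) are constant in training; their rules never fire",
                    sum(constant)))
  }
  rules <- data.table(segment = selected$segment, mz = selected$mz,
                      cutoff = vapply(fits, `[[`, 0, "cutoff"),
                      sign = as.integer(sign), weight = weight,
                      youden_j = vapply(fits, `[[`, 0, "j"))
  rules[, key := selected$key]
  setcolorder(rules, c("key", "segment", "mz", "cutoff", "sign", "weight", "youden_j"))
  predictor <- structure(list(rules = rules, k = nrow(rules),
                              weight_scheme = weight_scheme,
                              training_summary = NULL),
                         class = "wda_predictor")
  train_fm <- structure(list(values = X, features = fm$features, meta = NULL),
                        class = "feature_matrix")
  dfs <- predict_df(predictor, train_fm)
  pc <- perf_curve(dfs$df, y)
  predictor$training_summary <- list(
    n_cancer = sum(y), n_control = sum(!y),
    c_statistic = pc$auc,
    crossover_df = pc$crossover$df,
    sensitivity = pc$crossover$sens,
    specificity = pc$crossover$spec
  )
  predictor
}

#' @export
print.wda_predictor <- function(x, ...) {
  ts <- x$training_summary
  cat(sprintf("<wda_predictor> %d rules (weights sum to %.1f)\n",
              x$k, sum(x$rules$weight)))
  if (!is.null(ts)) {
    cat(sprintf("  training: %d/%d cancer/control, C = %.3f, sens %.1f%% / spec %.1f%% at DF = %.2f\n",
                ts$n_cancer, ts$n_control, ts$c_statistic,
                100 * ts$sensitivity, 100 * ts$specificity, ts$crossover_df))
  }
  invisible(x)
}

#' Discriminant-function values for a set of samples
#'
#' Applies a frozen WDA predictor: each rule fires when
#' `sign * (x - cutoff) > 0` (strict), and a sample's DF is the sum of the
#' weights of its firing rules. Only the feature values are consulted — no
#' clinical metadata enters the computation, which is the blinding contract
#' of the validation phase. A rule feature absent from the matrix scores as
#' intensity 0 (absence of signal).
#'
#' @param predictor A `wda_predictor`.
#' @param fm A `feature_matrix` of samples to score.
#' @return A `data.frame` with columns `sample_id` and `df`.
#' @export
predict_df <- function(predictor, fm) {
  stopifnot(inherits(predictor, "wda_predictor"), inherits(fm, "feature_matrix"))
  rules <- predictor$rules
  n <- nrow(fm$values)
  X <- matrix(0, n, nrow(rules))
  present <- rules$key %in% colnames(fm$values)
  X[, present] <- fm$values[, rules$key[present], drop = FALSE]
  fires <- sweep(sweep(X, 2, rules$cutoff, `-`), 2, rules$sign, `*`) > 0
  data.frame(sample_id = rownames(fm$values),
             df = as.numeric(fires %*% rules$weight),
             stringsAsFactors = FALSE)
}

#' Binary cancer calls from DF values at a cutoff
#'
#' A sample is called positive when its DF is strictly greater than the
#' cutoff (results equal to the cutoff are negative).
#'
#' @param dfs Numeric DF values, or the `data.frame` from [predict_df()].
#' @param df_cutoff Nonnegative DF threshold.
#' @return A logical vector, `TRUE` = positive for cancer.
#' @export
classify <- function(dfs, df_cutoff) {
  stopifnot(is.numeric(df_cutoff), length(df_cutoff) == 1, df_cutoff >= 0)
  if (is.data.frame(dfs)) dfs <- dfs$df
  dfs > df_cutoff
}

#' Serialize a WDA predictor to JSON
#'
#' @param predictor A `wda_predictor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wda <- function(predictor, path) {
  stopifnot(inherits(predictor, "wda_predictor"))
  jsonlite::write_json(
    list(rules = predictor$rules, k = predictor$k,
         weight_scheme = predictor$weight_scheme,
         training_summary = predictor$training_summary),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a WDA predictor from JSON
#'
#' @param path Path written by [write_wda()].
#' @return A `wda_predictor`.
#' @export
read_wda <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- as.data.table(x$rules)
  rules[, `:=`(segment = as.integer(segment), mz = as.integer(mz),
               sign = as.integer(sign))]
  structure(list(rules = rules, k = as.integer(x$k),
                 weight_scheme = x$weight_scheme,
                 training_summary = x$training_summary),
            class = "wda_predictor")
}
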