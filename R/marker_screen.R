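#' C-statistic (ROC AUC) of one feature for a binary outcome
#'
#' Computed as the Mann-Whitney concordance probability with midrank tie
#' handling: the probability that a randomly chosen cancer sample has a
#' higher value than a randomly chosen control, counting ties as 1/2. The
#' statistic is folded to `[0.5, 1]` and returned with its orientation
#' (+1 when the cancer class tends to have the higher intensity, -1
#' otherwise).
#'
#' @param values Numeric vector of per-sample intensities.
#' @param labels Binary outcome (logical, 0/1, or "positive"/"negative");
#'   `TRUE` = cancer. `NA` labels are dropped.
#' @return A list with `c_statistic` (folded, in `[0.5, 1]`), `orientation`
#'   (+1/-1), and `auc` (the raw, unfolded AUC of "cancer is higher").
#' @export
cstat <- function(values, labels) {
  labels <- as_binary_labels(labels)
  keep <- !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    bm_stop("both classes must be non-empty", "breathmark_degenerate_error")
  }
  r <- rank(values)                      # midranks
  a <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(c_statistic = max(a, 1 - a),
       orientation = if (a >= 0.5) 1L else -1L,
       auc = a)
}

# Column ranks of a samples x features matrix; AUC for every feature from
# the rank matrix and a label vector. Ranks do not depend on the labels, so
# one rank matrix serves the correct assignment and every permutation.
rank_matrix <- function(X) apply(X, 2, rank)

auc_from_ranks <- function(R, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (colSums(R[labels, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Monte-Carlo screen: per-feature C-statistics under correct and random
#' assignment
#'
#' Computes every feature's C-statistic under the correct cancer /
#' cancer-free assignment, then under `n_perm` random assignments. Each
#' random assignment is a single label permutation preserving class sizes
#' and shared across all features (subjects are permuted, not per-ion
#' values), so the inter-feature correlation structure of the null is
#' preserved. Permuted C-statistics are folded to `[0.5, 1]` by default,
#' matching the folding of the correct-assignment statistics; set
#' `fold_random = FALSE` to keep raw permuted AUCs.
#'
#' @param fm A `feature_matrix`.
#' @param labels Optional binary labels aligned with the rows of `fm`;
#'   default derives them with [screening_labels()] from `fm$meta`
#'   (tissue-confirmed cancer vs CT-negative controls). `NA` rows are
#'   excluded.
#' @param n_perm Number of random assignments (default 40). Must be >= 2
#'   (the curve SD is undefined otherwise).
#' @param seed Integer seed for the permutations.
#' @param fold_random Fold permuted C-statistics to `[0.5, 1]`
#'   (default `TRUE`).
#' @return An object of class `marker_scores`: list with `features`
#'   (`data.table` key/segment/mz), `c_correct`, `orientation`, `c_random`
#'   (features x `n_perm` matrix), class sizes, and the call parameters.
#' @export
monte_carlo_screen <- function(fm, labels = NULL, n_perm = 40, seed = 1L,
                               fold_random = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (n_perm < 2) {
    bm_stop("n_perm must be at least 2", "breathmark_validation_error")
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
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    bm_stop("both classes must be non-empty", "breathmark_degenerate_error")
  }
  R <- rank_matrix(X)
  a <- auc_from_ranks(R, y)
  c_random <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ab <- auc_from_ranks(R, sample(y))
      if (fold_random) pmax(ab, 1 - ab) else ab
    }, numeric(ncol(X)))
  })
  if (ncol(X) == 1) c_random <- matrix(c_random, nrow = 1)
  structure(list(features = copy(fm$features),
                 c_correct = pmax(a, 1 - a),
                 orientation = ifelse(a >= 0.5, 1L, -1L),
                 auc = a,
                 c_random = c_random,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fold_random = fold_random,
                 n_cancer = n1, n_control = n0,
                 sample_ids = rownames(X)),
            class = "marker_scores")
}

#' @export
print.marker_scores <- function(x, ...) {
  cat(sprintf("<marker_scores> %d features, %d/%d cancer/control, %d permutations\n",
              length(x$c_correct), x$n_cancer, x$n_control, x$n_perm))
  invisible(x)
}

#' Correct- and random-assignment count curves with non-randomness cutoff
#'
#' For an ascending grid of C-statistic values, counts how many features
#' reach at least that C under the correct assignment, and the mean and SD
#' (over permutations) of the same count under random assignment. The
#' cutoff is the smallest grid value where the mean random count is exactly
#' zero — i.e. no permuted C-statistic among all permutations reached it —
#' and the number of selected-eligible features is the correct-assignment
#' count there. `sigma_separation` measures how many random-count SDs
#' separate the two curves, evaluated at the largest grid point at or below
#' the cutoff where the random-count SD is still positive.
#'
#' @param scores A `marker_scores` object.
#' @param grid_step Grid spacing on the C axis (default 0.01).
#' @return An object of class `screen_curves`: list with `grid`,
#'   `count_correct`, `mean_count_random`, `sd_count_random`, `cutoff_c`,
#'   `n_selected`, `sigma_separation`, `sigma_at`.
#' @export
build_curves <- function(scores, grid_step = 0.01) {
  stopifnot(inherits(scores, "marker_scores"))
  if (!length(scores$c_correct)) {
    bm_stop("no scores to build curves from", "breathmark_validation_error")
  }
  grid <- seq(0.5, 1, by = grid_step)
  count_correct <- vapply(grid, function(x) sum(scores$c_correct >= x), numeric(1))
  counts_random <- vapply(grid, function(x) colSums(scores$c_random >= x),
                          numeric(scores$n_perm))   # n_perm x |grid|
  if (scores$n_perm == 1) counts_random <- matrix(counts_random, nrow = 1)
  mean_rand <- colMeans(counts_random)
  sd_rand <- apply(counts_random, 2, sd)
  zero <- which(mean_rand == 0)
  if (length(zero)) {
    cut_idx <- zero[1]
  } else {
    cut_idx <- length(grid)
    warning("random-assignment curve never reaches zero; using the top of the grid")
  }
  cutoff_c <- grid[cut_idx]
  n_selected <- count_correct[cut_idx]
  sig_cand <- which(sd_rand > 0 & grid <= cutoff_c)
  if (length(sig_cand)) {
    i <- max(sig_cand)
    sigma_separation <- (count_correct[i] - mean_rand[i]) / sd_rand[i]
    sigma_at <- grid[i]
  } else {
    sigma_separation <- NA_real_
    sigma_at <- NA_real_
  }
  structure(list(grid = grid, count_correct = count_correct,
                 mean_count_random = mean_rand, sd_count_random = sd_rand,
                 cutoff_c = cutoff_c, n_selected = n_selected,
                 sigma_separation = sigma_separation, sigma_at = sigma_at),
            class = "screen_curves")
}

#' @export
print.screen_curves <- function(x, ...) {
  cat(sprintf("<screen_curves> cutoff C = %.2f, %d features above it (separation %.1f sigma at C = %.2f)\n",
              x$cutoff_c, x$n_selected, x$sigma_separation, x$sigma_at))
  invisible(x)
}

#' Select the top-K biomarker features above the non-randomness cutoff
#'
#' Features with a correct-assignment C-statistic at or above the curve
#' cutoff, ordered by descending C-statistic with a deterministic
#' (segment, m/z) tie-break, truncated to `k`. With
#' `within_segment = TRUE` the ordering is segment-major (features ranked
#' within each retention-time segment first), an alternative reading of
#' per-segment ranking; the eligible set is identical.
#'
#' @param scores A `marker_scores` object.
#' @param curves The [build_curves()] result for the same scores.
#' @param k Maximum number of features to select (default 500).
#' @param within_segment Segment-major ordering (default `FALSE`, global
#'   ranking).
#' @return A `data.table` with `key`, `segment`, `mz`, `c_correct`,
#'   `orientation`, ordered as selected.
#' @export
select_top_k <- function(scores, curves, k = 500, within_segment = FALSE) {
  stopifnot(inherits(scores, "marker_scores"), inherits(curves, "screen_curves"),
            k >= 1)
  sel <- data.table(scores$features,
                    c_correct = scores$c_correct,
                    orientation = scores$orientation)
  sel <- sel[c_correct >= curves$cutoff_c]
  if (within_segment) {
    setorder(sel, segment, -c_correct, mz)
  } else {
    setorder(sel, -c_correct, segment, mz)
  }
  head(sel, k)
}

#' Run the full Monte-Carlo biomarker screen
#'
#' Convenience wrapper chaining [monte_carlo_screen()], [build_curves()]
#' and [select_top_k()].
#'
#' @inheritParams monte_carlo_screen
#' @inheritParams build_curves
#' @inheritParams select_top_k
#' @return An object of class `screen_result`: list with `scores`, `curves`,
#'   `selected`, `k`, `n_perm`, `seed`.
#' @export
screen_markers <- function(fm, labels = NULL, n_perm = 40, k = 500, seed = 1L,
                           grid_step = 0.01, fold_random = TRUE,
                           within_segment = FALSE) {
  scores <- monte_carlo_screen(fm, labels, n_perm = n_perm, seed = seed,
                               fold_random = fold_random)
  curves <- build_curves(scores, grid_step = grid_step)
  selected <- select_top_k(scores, curves, k = k, within_segment = within_segment)
  structure(list(scores = scores, curves = curves, selected = selected,
                 k = as.integer(k), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$curves)
  cat(sprintf("  selected %d of %d eligible features (k = %d)\n",
              nrow(x$selected), x$curves$n_selected, x$k))
  invisible(x)
}

#' Export screen curves as a plain table
#'
#' @param curves A `screen_curves` object.
#' @param path Optional CSV path; if given the table is also written there.
#' @return A `data.table` with one row per grid point.
#' @export
screen_curves_table <- function(curves, path = NULL) {
  stopifnot(inherits(curves, "screen_curves"))
  dt <- data.table(c_value = curves$grid,
                   count_correct = curves$count_correct,
                   mean_count_random = curves$mean_count_random,
                   sd_count_random = curves$sd_count_random)
  if (!is.null(path)) fwrite(dt, path)
  dt
}
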