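# Small builders shared across tests. Fixtures are generated in code, never
# stored on disk.

tiny_sim <- function(n_cancer = 25, n_control = 20, n_segments = 5,
                     ions_per_segment = 10, n_informative = 5,
                     target_auc = 0.75, seed = 101, ...) {
  sim_config(n_cancer = n_cancer, n_control = n_control,
             n_segments = n_segments, ions_per_segment = ions_per_segment,
             n_informative = n_informative, target_auc = target_auc,
             seed = seed, ...)
}

# one-sample ion table with an internal standard at rt 100
make_table <- function(sample_id = "s1",
                       rt = c(100, 100, 500),
                       mz = c(95, 43, 57),
                       intensity = c(1e6, 2e5, 1e4)) {
  ion_table(sample_id, data.frame(rt = rt, mz = mz, intensity = intensity))
}

# metadata row(s) for hand-built samples
make_meta <- function(sample_id, subject_id = sample_id, group = 1L,
                      cancer_status = "negative", lab = "A",
                      phase = "model_building", sample_kind = "breath") {
  data.frame(sample_id = sample_id, subject_id = subject_id, group = group,
             cancer_status = cancer_status, lab = lab, site = "site_DE",
             phase = phase, sample_kind = sample_kind,
             age = 60, pack_years = 30, sex = "M",
             stringsAsFactors = FALSE)
}

# exhaustive pairwise concordance count: the independent AUC oracle
brute_force_auc <- function(values, labels) {
  x1 <- values[labels]
  x0 <- values[!labels]
  tot <- 0
  for (a in x1) for (b in x0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(x1) * length(x0))
}

# feature matrix straight from a numeric matrix (for classifier unit tests)
fm_from_matrix <- function(X, meta = NULL) {
  feats <- breathmark:::parse_feature_keys(colnames(X))
  structure(list(values = X, features = feats, meta = meta),
            class = "feature_matrix")
}

# hand-built marker_scores object (for curve-construction tests)
scores_from_values <- function(c_correct, c_random, segment = NULL, mz = NULL) {
  p <- length(c_correct)
  if (is.null(segment)) segment <- seq_len(p) - 1L
  if (is.null(mz)) mz <- rep(43L, p)
  feats <- data.table::data.table(segment = as.integer(segment),
                                  mz = as.integer(mz))
  feats[, key := sprintf("seg%d_mz%d", segment, mz)]
  data.table::setcolorder(feats, c("key", "segment", "mz"))
  structure(list(features = feats, c_correct = c_correct,
                 orientation = rep(1L, p), auc = c_correct,
                 c_random = c_random, n_perm = ncol(c_random), seed = 1L,
                 fold_random = TRUE, n_cancer = 10L, n_control = 10L,
                 sample_ids = NULL),
            class = "marker_scores")
}
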