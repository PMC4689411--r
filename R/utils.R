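# Classed conditions so callers can distinguish failure modes programmatically.
bm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "breathmark_error"), call = call))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coerce labels (logical, 0/1, factor, "positive"/"negative") to logical,
# TRUE = cancer. NA passes through.
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) {
      bm_stop("numeric labels must be 0/1", "breathmark_validation_error")
    }
    return(labels == 1)
  }
  x <- as.character(labels)
  out <- rep(NA, length(x))
  out[x %in% c("positive", "cancer", "TRUE", "1")] <- TRUE
  out[x %in% c("negative", "control", "cancer-free", "FALSE", "0")] <- FALSE
  if (any(is.na(out) & !is.na(x) & !(x %in% c("", "unknown", "NA")))) {
    bm_stop("unrecognised label values", "breathmark_validation_error")
  }
  out
}

round_half_up <- function(x) floor(x + 0.5)

# Write a table with doubles rendered at full (17 significant digit)
# precision so that write-then-read reproduces values bit-exactly.
fwrite_exact <- function(dt, path) {
  dt <- copy(as.data.table(dt))
  for (col in names(dt)) {
    if (is.double(dt[[col]])) {
      set(dt, j = col, value = sub("e([+-])0(\\d\\d)$", "e\\1\\2",
                                   sprintf("%.17g", dt[[col]])))
    }
  }
  fwrite(dt, path, quote = FALSE)
  invisible(path)
}
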