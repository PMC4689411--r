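#' A diagnostic test's sensitivity/specificity profile
#'
#' @param name Test name (e.g. `"chest CT"`).
#' @param sens Sensitivity, fraction in `[0, 1]`.
#' @param spec Specificity, fraction in `[0, 1]`.
#' @return An object of class `test_profile`.
#' @export
test_profile <- function(name, sens, spec) {
  ok <- is.character(name) && length(name) == 1 &&
    is.numeric(sens) && sens >= 0 && sens <= 1 &&
    is.numeric(spec) && spec >= 0 && spec <= 1
  if (!ok) bm_stop("invalid test profile", "breathmark_validation_error")
  structure(list(name = name, sens = sens, spec = spec), class = "test_profile")
}

#' @export
print.test_profile <- function(x, ...) {
  cat(sprintf("<test_profile> %s: sensitivity %.1f%%, specificity %.1f%%\n",
              x$name, 100 * x$sens, 100 * x$spec))
  invisible(x)
}

#' Combine two diagnostic tests under an AND or OR positivity rule
#'
#' Under conditional independence of the two tests given disease status:
#' requiring both tests positive (`"both_positive"`) gives combined
#' sensitivity `sensA * sensB` and specificity
#' `1 - (1 - specA) * (1 - specB)` — sensitivity falls, specificity rises;
#' calling positive when either test is positive (`"either_positive"`)
#' gives sensitivity `1 - (1 - sensA) * (1 - sensB)` and specificity
#' `specA * specB` — sensitivity rises, specificity falls.
#'
#' @param a,b `test_profile` objects.
#' @param rule `"both_positive"` or `"either_positive"`.
#' @return A `test_profile` for the combined test.
#' @export
combine_tests <- function(a, b, rule = c("both_positive", "either_positive")) {
  stopifnot(inherits(a, "test_profile"), inherits(b, "test_profile"))
  rule <- match.arg(rule)
  if (rule == "both_positive") {
    sens <- a$sens * b$sens
    spec <- 1 - (1 - a$spec) * (1 - b$spec)
    label <- "both positive"
  } else {
    sens <- 1 - (1 - a$sens) * (1 - b$sens)
    spec <- a$spec * b$spec
    label <- "either positive"
  }
  test_profile(sprintf("%s + %s (%s)", a$name, b$name, label), sens, spec)
}

check_prevalence <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      prevalence <= 0 || prevalence >= 1) {
    bm_stop("prevalence must lie strictly between 0 and 1",
            "breathmark_validation_error")
  }
}

#' Positive predictive value of a test at a given prevalence
#'
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`.
#'
#' @param t A `test_profile`.
#' @param prevalence Disease prevalence, strictly in (0, 1).
#' @return PPV as a fraction.
#' @export
ppv <- function(t, prevalence) {
  stopifnot(inherits(t, "test_profile"))
  check_prevalence(prevalence)
  t$sens * prevalence /
    (t$sens * prevalence + (1 - t$spec) * (1 - prevalence))
}

#' Negative predictive value of a test at a given prevalence
#'
#' `NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#'
#' @inheritParams ppv
#' @return NPV as a fraction.
#' @export
npv <- function(t, prevalence) {
  stopifnot(inherits(t, "test_profile"))
  check_prevalence(prevalence)
  t$spec * (1 - prevalence) /
    (t$spec * (1 - prevalence) + (1 - t$sens) * prevalence)
}

#' Expected screening outcome counts in a population
#'
#' Expected true positives, false negatives, true negatives and false
#' positives when `n_screened` people at the given prevalence are screened
#' with the test. Exact (fractional) counts are kept internally; rounded
#' counts are for display.
#'
#' @inheritParams ppv
#' @param n_screened Number of people screened (>= 1).
#' @return A list with `exact` and `rounded`, each a named numeric vector
#'   `(tp, fn, tn, fp)`.
#' @export
population_counts <- function(t, prevalence, n_screened) {
  stopifnot(inherits(t, "test_profile"))
  check_prevalence(prevalence)
  if (!is.numeric(n_screened) || n_screened < 1) {
    bm_stop("n_screened must be at least 1", "breathmark_validation_error")
  }
  exact <- c(tp = t$sens * prevalence * n_screened,
             fn = (1 - t$sens) * prevalence * n_screened,
             tn = t$spec * (1 - prevalence) * n_screened,
             fp = (1 - t$spec) * (1 - prevalence) * n_screened)
  list(exact = exact, rounded = round(exact))
}

#' Full combined-screening outcome model for two tests
#'
#' Evaluates each test alone and their AND/OR combinations at the given
#' prevalence: sensitivity, specificity, PPV, NPV, and expected outcome
#' counts among `n_screened` people. Assumes the two tests err
#' conditionally independently given disease status.
#'
#' @param a,b `test_profile` objects (e.g. chest CT and the breath test).
#' @param prevalence Disease prevalence, strictly in (0, 1).
#' @param n_screened Population size (default one million).
#' @return An object of class `screening_outcome`: a `data.table` with one
#'   row per test/rule (`test`, `sens`, `spec`, `ppv`, `npv`, `tp`, `fn`,
#'   `tn`, `fp`), plus attributes `prevalence` and `n_screened`.
#' @export
screening_outcome <- function(a, b, prevalence, n_screened = 1e6) {
  profiles <- list(a, b,
                   combine_tests(a, b, "both_positive"),
                   combine_tests(a, b, "either_positive"))
  rows <- lapply(profiles, function(t) {
    cnt <- population_counts(t, prevalence, n_screened)
    data.table(test = t$name, sens = t$sens, spec = t$spec,
               ppv = ppv(t, prevalence), npv = npv(t, prevalence),
               tp = cnt$exact[["tp"]], fn = cnt$exact[["fn"]],
               tn = cnt$exact[["tn"]], fp = cnt$exact[["fp"]])
  })
  out <- rbindlist(rows)
  setattr(out, "prevalence", prevalence)
  setattr(out, "n_screened", n_screened)
  setattr(out, "class", c("screening_outcome", class(out)))
  out
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat(sprintf("<screening_outcome> prevalence %.2f%%, %s screened\n",
              100 * attr(x, "prevalence"),
              format(attr(x, "n_screened"), big.mark = ",")))
  for (i in seq_len(nrow(x))) {
    r <- x[i]
    cat(sprintf("  %-40s sens %6.2f%%  spec %6.2f%%  PPV %5.2f%%  NPV %6.2f%%  FP %s  FN %s\n",
                r$test, 100 * r$sens, 100 * r$spec, 100 * r$ppv, 100 * r$npv,
                format(round(r$fp), big.mark = ","),
                format(round(r$fn), big.mark = ",")))
  }
  invisible(x)
}
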