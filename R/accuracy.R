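#' Confusion counts for one test on an integrated dataset
#'
#' Cross-classifies the test's binary call against the cystoscopy truth.
#' Scope `"measured_only"` uses only cells whose provenance is `measured`;
#' `"imputed_full"` uses every non-missing cell (measured and imputed).
#'
#' @param ds Integrated cohort data frame.
#' @param test One of the four test names.
#' @param scope `"measured_only"` or `"imputed_full"`.
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @export
confusion_counts <- function(ds, test,
                             scope = c("measured_only", "imputed_full")) {
  test <- match.arg(test, DX_TESTS)
  scope <- match.arg(scope)
  usable <- !is.na(ds[[test]])
  if (scope == "measured_only") {
    usable <- usable & ds[[src_col(test)]] == "measured"
  }
  pos <- binary_positive(test, ds[[test]])
  uc <- ds$truth == "UC"
  counts <- c(TP = sum(usable & uc & pos), FN = sum(usable & uc & !pos),
              TN = sum(usable & !uc & !pos), FP = sum(usable & !uc & pos))
  if (counts[["TP"]] + counts[["FN"]] == 0L ||
      counts[["TN"]] + counts[["FP"]] == 0L) {
    stop(sprintf("confusion_counts: no usable %s values in the %s group under scope %s",
                 test,
                 if (counts[["TP"]] + counts[["FN"]] == 0L) "UC" else "non-UC",
                 scope), call. = FALSE)
  }
  counts
}

## Wald CI on the logit scale for k successes out of n — the interval an
## intercept-only logistic regression reports. Boundary proportions (k = 0
## or k = n) get a 0.5 continuity correction for the CI only.
logit_wald_ci <- function(k, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  kk <- k; nn <- n
  if (k == 0L || k == n) {
    kk <- k + 0.5
    nn <- n + 1
  }
  lo <- stats::qlogis(kk / nn) - z * sqrt(1 / kk + 1 / (nn - kk))
  hi <- stats::qlogis(kk / nn) + z * sqrt(1 / kk + 1 / (nn - kk))
  c(stats::plogis(lo), stats::plogis(hi))
}

#' Sensitivity and specificity with confidence intervals
#'
#' Point estimates are the plain proportions TP/(TP+FN) and TN/(TN+FP),
#' reported as percentages. Confidence intervals come from an intercept-only
#' logistic model per truth group, i.e. the Wald interval on the logit
#' scale, `logit(p) +/- z * sqrt(1/k + 1/(n-k))`, back-transformed. At a
#' boundary proportion (0 or 1) a 0.5 continuity correction is applied to
#' the CI only; the point estimate is unchanged.
#'
#' @param counts Named vector `c(TP, FN, TN, FP)` from [confusion_counts()].
#' @param level Confidence level, default 0.95.
#' @param test Optional test name carried into the result.
#' @param scope Optional scope label carried into the result.
#' @return One-row data frame: `test`, `scope`, `sens`, `sens_lo`,
#'   `sens_hi`, `spec`, `spec_lo`, `spec_hi` (percent), and the four counts.
#' @examples
#' sens_spec_ci(c(TP = 8, FN = 2, TN = 90, FP = 10))
#' @export
sens_spec_ci <- function(counts, level = 0.95, test = NA_character_,
                         scope = NA_character_) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  stopifnot(tp + fn > 0, tn + fp > 0)
  sens_ci <- logit_wald_ci(tp, tp + fn, level)
  spec_ci <- logit_wald_ci(tn, tn + fp, level)
  data.frame(
    test = test, scope = scope,
    sens = 100 * tp / (tp + fn),
    sens_lo = 100 * sens_ci[1], sens_hi = 100 * sens_ci[2],
    spec = 100 * tn / (tn + fp),
    spec_lo = 100 * spec_ci[1], spec_hi = 100 * spec_ci[2],
    tp = tp, fn = fn, tn = tn, fp = fp,
    stringsAsFactors = FALSE
  )
}

#' Accuracy table for every test
#'
#' Convenience wrapper: [confusion_counts()] then [sens_spec_ci()] for each
#' of the four tests under one scope.
#'
#' @inheritParams confusion_counts
#' @param level Confidence level.
#' @return Data frame with one row per test.
#' @export
test_accuracy <- function(ds, scope = c("measured_only", "imputed_full"),
                          level = 0.95) {
  scope <- match.arg(scope)
  do.call(rbind, lapply(DX_TESTS, function(t) {
    sens_spec_ci(confusion_counts(ds, t, scope), level, test = t,
                 scope = scope)
  }))
}
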