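pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Signal-to-noise separation index for one variable
#'
#' Two-class separation score used to rank variables: the absolute
#' difference between the mean value in the UC ("signal") and non-UC
#' ("noise") groups, scaled by the sum of the two groups' population
#' standard deviations,
#' \deqn{\mathrm{SNR} = |\mu_{UC} - \mu_{nonUC}| / (\sigma_{UC} + \sigma_{nonUC}).}
#' A higher index means greater separation between the groups and hence a
#' more discriminative test. Missing values are removed before computing
#' (complete cases per variable).
#'
#' @param values Numeric vector (coded test results or a covariate).
#' @param truth Character vector, `"UC"` or `"nonUC"`, same length.
#' @param variable Name used in error messages.
#' @return Non-negative scalar. If both group sds are zero the index is 0
#'   when the means are equal and an error (undefined ratio) otherwise.
#' @examples
#' snr_index(c(2, 2, 2, 1, 1, 1, 1, 2),
#'           c("UC", "UC", "UC", "UC", "nonUC", "nonUC", "nonUC", "nonUC"))
#' @export
snr_index <- function(values, truth, variable = "variable") {
  keep <- !is.na(values)
  values <- values[keep]
  truth <- truth[keep]
  sig <- values[truth == "UC"]
  noi <- values[truth == "nonUC"]
  if (length(sig) == 0L || length(noi) == 0L) {
    stop(sprintf("snr_index: empty %s group for '%s' after missing-value removal",
                 if (length(sig) == 0L) "UC" else "non-UC", variable),
         call. = FALSE)
  }
  dmean <- abs(mean(sig) - mean(noi))
  denom <- pop_sd(sig) + pop_sd(noi)
  if (denom == 0) {
    if (dmean == 0) return(0)
    stop(sprintf("snr_index: zero spread with unequal means for '%s' (undefined ratio)",
                 variable), call. = FALSE)
  }
  dmean / denom
}

#' Rank tests (and demographics) by signal-to-noise separation
#'
#' Computes [snr_index()] for the four diagnostic tests plus age and gender
#' on an integrated dataset and orders them by descending index, ties broken
#' alphabetically. Coding `"multilevel"` (default) uses the raw 1-4 cytology
#' code, as in the initial ranking of the measured integrated dataset;
#' `"binary"` collapses every test via [to_binary()] (coded 1/2) for
#' sensitivity analysis.
#'
#' @param ds Integrated cohort data frame.
#' @param coding `"multilevel"` or `"binary"`.
#' @return Data frame with one row per variable: `variable`, `n_uc`,
#'   `n_nonuc`, `mean_uc`, `mean_nonuc`, `sd_uc`, `sd_nonuc` (population
#'   sds), `snr`, `rank`. A variable with data in only one group gets `NA`
#'   index and no rank; a variable separating the groups perfectly (zero
#'   spread in both, unequal means) ranks first with an infinite index.
#' @export
rank_tests <- function(ds, coding = c("multilevel", "binary")) {
  coding <- match.arg(coding)
  vars <- c(DX_TESTS, "age", "gender")
  rows <- lapply(vars, function(v) {
    x <- ds[[v]]
    if (v %in% DX_TESTS && coding == "binary") {
      x <- ifelse(binary_positive(v, x), 2, 1)
    }
    keep <- !is.na(x)
    sig <- x[keep & ds$truth == "UC"]
    noi <- x[keep & ds$truth == "nonUC"]
    ## a perfectly separating variable (zero spread in both groups, unequal
    ## means) dominates the ranking rather than erroring out
    snr <- if (length(sig) == 0L || length(noi) == 0L) {
      NA_real_
    } else if (pop_sd(sig) + pop_sd(noi) == 0 && mean(sig) != mean(noi)) {
      Inf
    } else {
      snr_index(x, ds$truth, v)
    }
    data.frame(
      variable = v, n_uc = length(sig), n_nonuc = length(noi),
      mean_uc = if (length(sig)) mean(sig) else NA_real_,
      mean_nonuc = if (length(noi)) mean(noi) else NA_real_,
      sd_uc = if (length(sig)) pop_sd(sig) else NA_real_,
      sd_nonuc = if (length(noi)) pop_sd(noi) else NA_real_,
      snr = snr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$snr, out$variable, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$rank <- NA_integer_
  out$rank[!is.na(out$snr)] <- seq_len(sum(!is.na(out$snr)))
  rownames(out) <- NULL
  out
}
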