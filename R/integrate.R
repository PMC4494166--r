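n_tests_present <- function(records) {
  rowSums(!is.na(as.matrix(records[, DX_TESTS])))
}

#' Merge per-study records into one integrated dataset
#'
#' Applies the study's discard and reclassification rules: records lacking a
#' cystoscopy-based truth are discarded, then records with fewer than two
#' non-missing test results are discarded (age and gender never count toward
#' that threshold), and "other-cause" diagnoses (e.g. kidney stones) are
#' reclassified as non-UC. The result is a single dataset with binary truth
#' and missing cells left in place for downstream imputation.
#'
#' Unknown-truth is checked before the single-test rule, so a record failing
#' both is audited under `no_truth`.
#'
#' @param records Cohort data frame (possibly several studies' rows bound
#'   together).
#' @return The integrated cohort data frame with attribute `"audit"`: a list
#'   with `input_n`, `retained_n`, `discarded` (counts by reason, overall and
#'   per dataset) and `reclassified_other`.
#' @examples
#' ds <- integrate_cohort(generate_cohort(seed = 1))
#' nrow(ds)                  # 939
#' attr(ds, "audit")$discarded$total
#' @export
integrate_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("integrate_cohort: empty input", call. = FALSE)
  }
  bad <- validate_record(records)
  if (nrow(bad) > 0L) {
    stop(sprintf("input fails validation (%d violation(s))", nrow(bad)),
         call. = FALSE)
  }
  records <- ensure_provenance(records)
  no_truth <- records$truth == "unknown"
  single_test <- !no_truth & n_tests_present(records) < 2L
  keep <- !no_truth & !single_test
  reclass <- keep & records$truth == "other"

  audit <- list(
    input_n = nrow(records),
    retained_n = sum(keep),
    discarded = list(
      total = sum(!keep),
      no_truth = sum(no_truth),
      single_test = sum(single_test),
      by_dataset = stats::aggregate(
        cbind(no_truth = no_truth, single_test = single_test),
        by = list(dataset_id = records$dataset_id), FUN = sum)
    ),
    reclassified_other = sum(reclass)
  )
  if (sum(keep) == 0L) {
    err <- simpleError("integrate_cohort: all records discarded")
    err$audit <- audit
    stop(err)
  }
  out <- records[keep, , drop = FALSE]
  out$truth[out$truth == "other"] <- "nonUC"
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Missing-cell summary of an integrated dataset
#'
#' Exact counts of missing cells per test, overall and per
#' (dataset, test) block; age and gender are always complete.
#'
#' @param ds Integrated cohort data frame (from [integrate_cohort()]).
#' @return List with `per_test` (named integer vector over the four tests)
#'   and `per_block` (data frame `dataset_id`, `test`, `n_missing`,
#'   `n_records`).
#' @examples
#' ds <- integrate_cohort(generate_cohort(seed = 1))
#' missingness_summary(ds)$per_test  # fish 622, cxbladder 193, ...
#' @export
missingness_summary <- function(ds) {
  per_test <- vapply(DX_TESTS, function(t) sum(is.na(ds[[t]])), integer(1))
  blocks <- expand.grid(dataset_id = sort(unique(ds$dataset_id)),
                        test = DX_TESTS, stringsAsFactors = FALSE)
  blocks$n_missing <- mapply(function(d, t) {
    sum(is.na(ds[[t]][ds$dataset_id == d]))
  }, blocks$dataset_id, blocks$test)
  blocks$n_records <- vapply(blocks$dataset_id,
                             function(d) sum(ds$dataset_id == d), integer(1))
  blocks <- blocks[order(blocks$dataset_id, blocks$test), ]
  rownames(blocks) <- NULL
  list(per_test = per_test, per_block = blocks)
}
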