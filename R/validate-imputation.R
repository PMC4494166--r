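#' Leave-one-out cross-validation accuracy of an imputation backend
#'
#' For each evaluated record of a complete pool, the record's known target
#' value is hidden, imputed from all other records, and compared with the
#' truth; the accuracy is the percentage of correctly imputed values.
#' Correctness is judged on the binary diagnostic mapping by default (the
#' downstream use of every imputed value), with `strict = TRUE` comparing
#' raw codes (relevant for 4-level cytology).
#'
#' @param pool Data frame, complete on `inputs` and `target`.
#' @param inputs Character vector of input variable names.
#' @param target Target test name.
#' @param backend A `dx_backend`.
#' @param strict Compare raw codes instead of binary outcomes.
#' @param max_n Evaluate at most this many records (seeded subsample via the
#'   backend seed) to bound the cost on large pools; all remaining records
#'   still serve as training data for every held-out prediction. `Inf`
#'   evaluates every record.
#' @return List with `accuracy` (percent), `n_eval`, `n_correct`.
#' @export
loo_accuracy <- function(pool, inputs, target, backend, strict = FALSE,
                         max_n = Inf) {
  n <- nrow(pool)
  min_n <- if (backend$kind == "knn") backend$k + 1L else length(inputs) + 2L
  if (n < min_n) {
    stop(sprintf("loo_accuracy: pool of %d record(s) too small for backend %s (need >= %d)",
                 n, backend$kind, min_n), call. = FALSE)
  }
  eval_idx <- seq_len(n)
  if (is.finite(max_n) && n > max_n) {
    eval_idx <- with_seed(backend$seed, sort(sample(n, max_n)))
  }
  pred <- vapply(eval_idx, function(i) {
    impute_with_backend(pool[-i, , drop = FALSE], pool[i, , drop = FALSE],
                        inputs, target, backend)
  }, integer(1))
  actual <- pool[[target]][eval_idx]
  correct <- if (strict) pred == actual else
    to_binary(target, pred) == to_binary(target, actual)
  list(accuracy = 100 * mean(correct), n_eval = length(eval_idx),
       n_correct = sum(correct))
}

#' Measured-versus-imputed accuracy distortion for one test
#'
#' The change a test's sensitivity and specificity undergo when estimated on
#' the fully imputed dataset instead of the measured cells only; small
#' values mean the imputation is consistent with the measured data. Signs
#' follow the convention difference = measured - imputed.
#'
#' @param measured Integrated cohort data frame (pre-imputation).
#' @param imputed The same cohort after [run_plan()].
#' @param test Test name.
#' @return List with `sens_diff`, `spec_diff` (percentage points, measured
#'   minus imputed) and `avg_abs_diff` = (|sens_diff| + |spec_diff|) / 2.
#' @export
before_after <- function(measured, imputed, test) {
  if (nrow(measured) != nrow(imputed)) {
    stop("before_after: datasets cover different numbers of subjects",
         call. = FALSE)
  }
  m <- sens_spec_ci(confusion_counts(measured, test, "measured_only"))
  i <- sens_spec_ci(confusion_counts(imputed, test, "imputed_full"))
  sens_diff <- m$sens - i$sens
  spec_diff <- m$spec - i$spec
  list(sens_diff = sens_diff, spec_diff = spec_diff,
       avg_abs_diff = (abs(sens_diff) + abs(spec_diff)) / 2)
}

#' Per-method means of a validation report
#'
#' Arithmetic mean over the tests of each numeric column, per
#' (backend, mode); signed columns are averaged with their signs.
#'
#' @param report Data frame as produced by [validate_imputation()] (columns
#'   `test`, `backend`, `mode`, `loo_acc`, `sens_diff`, `spec_diff`,
#'   `avg_abs_diff`).
#' @return Data frame with one `mean_for_method` row per (backend, mode).
#' @export
method_summary <- function(report) {
  stopifnot(nrow(report) > 0L)
  agg <- stats::aggregate(
    report[, c("loo_acc", "sens_diff", "spec_diff", "avg_abs_diff")],
    by = list(backend = report$backend, mode = report$mode), FUN = mean)
  agg$test <- "mean_for_method"
  agg[, c("test", "backend", "mode", "loo_acc", "sens_diff", "spec_diff",
          "avg_abs_diff")]
}

## The (step, pool, inputs) triples of a plan that target one test; LOO for
## a test aggregates correct/evaluated over the pools of its steps.
plan_pools_for_test <- function(ds, plan, test, supervised) {
  ds$.truth_code <- truth_code(ds$truth)
  out <- list()
  for (s in plan$steps) {
    if (s$target_variable != test) next
    inputs <- s$input_variables
    if (supervised) inputs <- c(inputs, ".truth_code")
    pool <- ds[ds$dataset_id %in% s$training_datasets & !is.na(ds[[test]]) &
                 rowSums(is.na(ds[, inputs, drop = FALSE])) == 0L, ,
               drop = FALSE]
    out[[length(out) + 1L]] <- list(step = s$step_index, pool = pool,
                                    inputs = inputs)
  }
  out
}

#' Cross-validate imputation backends and report accuracy distortion
#'
#' For every requested backend and mode this runs the plan on the integrated
#' dataset, scores each test's leave-one-out imputation accuracy on the
#' training pools of the steps that impute it (aggregating correct
#' predictions across steps), and computes the measured-versus-imputed
#' sensitivity/specificity differences. Per-method mean rows are appended
#' and the best method under the lexicographic objective (highest mean LOO
#' accuracy, then lowest mean average absolute difference) is identified.
#'
#' @param ds Integrated cohort data frame.
#' @param backends Character vector of backend labels among
#'   `"3nn","5nn","10nn","mlr","mlp"`.
#' @param modes Character vector among `"supervised"`, `"unsupervised"`.
#' @param plan A `dx_plan`; default [canonical_plan()].
#' @param seed Integer seed for MLP initialization and LOO subsampling.
#' @param loo_max_n Per-step cap on LOO evaluations (see [loo_accuracy()]).
#' @return List with `report` (per test x backend x mode rows plus
#'   `mean_for_method` rows) and `best` (backend/mode of the winning
#'   method).
#' @export
validate_imputation <- function(ds, backends = c("3nn", "5nn", "10nn",
                                                 "mlr", "mlp"),
                                modes = c("supervised", "unsupervised"),
                                plan = canonical_plan(), seed = 1L,
                                loo_max_n = 150L) {
  rows <- list()
  for (b in backends) {
    for (mode in modes) {
      supervised <- mode == "supervised"
      backend <- parse_backend(b, supervised = supervised, seed = seed)
      imputed <- run_plan(ds, plan, backend)
      for (t in DX_TESTS) {
        pools <- plan_pools_for_test(ds, plan, t, supervised)
        loo <- NA_real_
        if (length(pools) > 0L) {
          tot_eval <- 0L
          tot_correct <- 0L
          for (p in pools) {
            r <- loo_accuracy(p$pool, p$inputs, t, backend,
                              max_n = loo_max_n)
            tot_eval <- tot_eval + r$n_eval
            tot_correct <- tot_correct + r$n_correct
          }
          loo <- 100 * tot_correct / tot_eval
        }
        ba <- before_after(ds, imputed, t)
        rows[[length(rows) + 1L]] <- data.frame(
          test = t, backend = b, mode = mode, loo_acc = loo,
          sens_diff = ba$sens_diff, spec_diff = ba$spec_diff,
          avg_abs_diff = ba$avg_abs_diff, stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  summary <- method_summary(report[!is.na(report$loo_acc), , drop = FALSE])
  ord <- order(-summary$loo_acc, summary$avg_abs_diff)
  best <- summary[ord[1L], c("backend", "mode")]
  list(report = rbind(report, summary[, names(report), drop = FALSE]),
       best = best)
}
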