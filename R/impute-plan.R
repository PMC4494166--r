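new_plan <- function(steps, mode) {
  structure(list(steps = steps, mode = mode), class = "dx_plan")
}

new_step <- function(step_index, training_datasets, input_variables,
                     target_dataset, target_variable,
                     expected_count = NA_integer_) {
  stopifnot(!(target_variable %in% input_variables))
  list(step_index = step_index,
       training_datasets = as.integer(training_datasets),
       input_variables = input_variables,
       target_dataset = as.integer(target_dataset),
       target_variable = target_variable,
       expected_count = as.integer(expected_count))
}

#' The canonical seven-step imputation plan
#'
#' The published order of execution for the five-study design, fewest
#' missing cells first: (1) NMP22 then (2) cytology within the complete
#' study (Dataset 5); (3) Cxbladder Detect in Dataset 4 trained on Datasets
#' 1, 4, 5; (4) NMP22 in Datasets 2 and 3 trained on all five; (5-7) FISH in
#' Datasets 3, 2 and 1, each trained on the target study plus Datasets 4 and
#' 5. `expected_count` carries the printed number of cells each step
#' imputes; it is informational, not enforced. The printed counts for step 4
#' (80 + 80) exceed Dataset 3's analyzed size (68), so that step's expected
#' count is left `NA`; see the package vignette.
#'
#' @return A `dx_plan` with seven steps.
#' @examples
#' plan <- canonical_plan()
#' length(plan$steps)  # 7
#' @export
canonical_plan <- function() {
  base <- c("age", "gender")
  steps <- list(
    new_step(1L, 5L, c(base, "cytology", "fish", "cxbladder"), 5L, "nmp22", 2L),
    new_step(2L, 5L, c(base, "nmp22", "fish", "cxbladder"), 5L, "cytology", 3L),
    new_step(3L, c(1L, 4L, 5L), c(base, "cytology", "nmp22"), 4L, "cxbladder", 193L),
    new_step(4L, 1:5, c(base, "cytology", "cxbladder"), c(2L, 3L), "nmp22", NA),
    new_step(5L, c(3L, 4L, 5L), c(base, "cytology", "cxbladder"), 3L, "fish", 68L),
    new_step(6L, c(2L, 4L, 5L), c(base, "cytology", "cxbladder"), 2L, "fish", 80L),
    new_step(7L, c(1L, 4L, 5L), c(base, "cytology", "cxbladder"), 1L, "fish", 474L)
  )
  new_plan(steps, "canonical")
}

#' @export
print.dx_plan <- function(x, ...) {
  cat(sprintf("Imputation plan (%s), %d step(s):\n", x$mode, length(x$steps)))
  for (s in x$steps) {
    cat(sprintf("  %d. D%s %s <- [%s] trained on D%s%s\n",
                s$step_index, paste(s$target_dataset, collapse = "+"),
                s$target_variable, paste(s$input_variables, collapse = ","),
                paste(s$training_datasets, collapse = ","),
                if (is.na(s$expected_count)) "" else
                  sprintf(" (%d cells)", s$expected_count)))
  }
  invisible(x)
}

#' Derive a step-wise imputation plan automatically
#'
#' Greedy dependency-aware ordering of (dataset, test) missing blocks:
#' among blocks whose training pool is non-empty, the block with the fewest
#' missing cells is imputed first, ties broken by test name then dataset id;
#' pools are re-evaluated after each step (cells scheduled for imputation
#' count as available for later steps). A block's input variables are age,
#' gender and every other test that is non-missing on all of the block's
#' query records; its training pool is every record with the target and all
#' those inputs non-missing.
#'
#' @param ds Integrated cohort data frame.
#' @return A `dx_plan`; empty (zero steps) for a complete dataset.
#' @export
auto_plan <- function(ds) {
  avail <- !is.na(as.matrix(ds[, DX_TESTS]))
  steps <- list()
  idx <- 1L
  repeat {
    blocks <- list()
    for (d in sort(unique(ds$dataset_id))) {
      in_d <- ds$dataset_id == d
      for (t in DX_TESTS) {
        n_missing <- sum(in_d & !avail[, t])
        if (n_missing == 0L) next
        queries <- in_d & !avail[, t]
        others <- setdiff(DX_TESTS, t)
        inputs <- c("age", "gender",
                    others[colSums(!avail[queries, others, drop = FALSE]) == 0L])
        pool <- avail[, t] &
          rowSums(!avail[, intersect(inputs, DX_TESTS), drop = FALSE]) == 0L
        blocks[[length(blocks) + 1L]] <- list(
          dataset = d, test = t, n_missing = n_missing, inputs = inputs,
          pool_datasets = sort(unique(ds$dataset_id[pool])),
          pool_n = sum(pool))
      }
    }
    if (length(blocks) == 0L) break
    eligible <- Filter(function(b) b$pool_n > 0L, blocks)
    if (length(eligible) == 0L) {
      stop(sprintf("auto_plan: deadlock; blocked block(s): %s",
                   paste(vapply(blocks, function(b)
                     sprintf("(D%d, %s)", b$dataset, b$test), character(1)),
                     collapse = ", ")), call. = FALSE)
    }
    ord <- order(vapply(eligible, `[[`, integer(1), "n_missing"),
                 vapply(eligible, `[[`, character(1), "test"),
                 vapply(eligible, `[[`, integer(1), "dataset"))
    b <- eligible[[ord[1L]]]
    steps[[idx]] <- new_step(idx, b$pool_datasets, b$inputs, b$dataset,
                             b$test, b$n_missing)
    avail[ds$dataset_id == b$dataset, b$test] <- TRUE
    idx <- idx + 1L
  }
  new_plan(steps, "auto")
}

## Truth as a numeric input for supervised imputation: nonUC 1, UC 2,
## matching the 1-based coding of the tests.
truth_code <- function(truth) ifelse(truth == "UC", 2, 1)

#' Execute an imputation plan
#'
#' Runs the plan's steps in order with one backend. Supervised mode appends
#' the clinical truth to every step's inputs. Measured cells are never
#' modified; each imputed cell gets provenance `imputed`. Previously imputed
#' cells serve as inputs only where a step's input set requires them. Each
#' step's training pool is logged with its fraction of measured (as opposed
#' to imputed) test cells; a fraction below 70 % is a warning, not an error,
#' since the published process states that level as a property, not a gate.
#'
#' @param ds Integrated cohort data frame.
#' @param plan A `dx_plan` ([canonical_plan()], [auto_plan()], or built by
#'   hand).
#' @param backend A `dx_backend` ([backend_config()]); its `supervised` flag
#'   can be overridden with `supervised`.
#' @param supervised Optional logical overriding `backend$supervised`.
#' @return The imputed cohort data frame with attribute `"impute_log"`, a
#'   data frame with one row per step (`step`, `target_dataset`, `target`,
#'   `n_imputed`, `pool_n`, `measured_fraction`).
#' @examples
#' ds <- integrate_cohort(generate_cohort(seed = 1))
#' imp <- run_plan(ds, canonical_plan(), backend_config("knn", k = 3))
#' sum(is.na(imp[dxrank:::DX_TESTS]))  # 0
#' @export
run_plan <- function(ds, plan, backend = backend_config("knn", k = 3L),
                     supervised = NULL) {
  stopifnot(inherits(plan, "dx_plan"), inherits(backend, "dx_backend"))
  if (!is.null(supervised)) backend$supervised <- isTRUE(supervised)
  ds$.truth_code <- truth_code(ds$truth)
  log_rows <- list()
  for (s in plan$steps) {
    inputs <- s$input_variables
    if (backend$supervised) inputs <- c(inputs, ".truth_code")
    step_backend <- backend
    step_backend$seed <- backend$seed + s$step_index  # independent MLP inits
    target <- s$target_variable
    q_idx <- which(ds$dataset_id %in% s$target_dataset & is.na(ds[[target]]))
    if (length(q_idx) == 0L) next
    complete_q <- q_idx[rowSums(is.na(ds[q_idx, inputs, drop = FALSE])) == 0L]
    if (length(complete_q) < length(q_idx)) {
      warning(sprintf("step %d: %d query record(s) incomplete on inputs, left missing",
                      s$step_index, length(q_idx) - length(complete_q)))
    }
    pool <- which(ds$dataset_id %in% s$training_datasets &
                    !is.na(ds[[target]]) &
                    rowSums(is.na(ds[, inputs, drop = FALSE])) == 0L)
    if (length(pool) == 0L) {
      stop(sprintf("run_plan: step %d (D%s, %s) has an empty training pool",
                   s$step_index, paste(s$target_dataset, collapse = "+"),
                   target), call. = FALSE)
    }
    cell_vars <- c(intersect(inputs, DX_TESTS), target)
    src <- as.matrix(ds[pool, src_col(cell_vars), drop = FALSE])
    measured_fraction <- mean(src == "measured")
    if (measured_fraction < 0.70) {
      warning(sprintf("step %d: training pool is only %.0f%% measured data (target >= 70%%)",
                      s$step_index, 100 * measured_fraction))
    }
    if (length(complete_q) > 0L) {
      codes <- impute_with_backend(ds[pool, , drop = FALSE],
                                   ds[complete_q, , drop = FALSE],
                                   inputs, target, step_backend)
      ds[[target]][complete_q] <- codes
      ds[[src_col(target)]][complete_q] <- "imputed"
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = s$step_index,
      target_dataset = paste(s$target_dataset, collapse = "+"),
      target = target, n_imputed = length(complete_q),
      pool_n = length(pool), measured_fraction = measured_fraction,
      stringsAsFactors = FALSE)
  }
  ds$.truth_code <- NULL
  attr(ds, "impute_log") <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), target_dataset = character(),
               target = character(), n_imputed = integer(),
               pool_n = integer(), measured_fraction = numeric())
  ds
}
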