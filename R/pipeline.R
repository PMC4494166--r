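#' Pipeline configuration
#'
#' One structured document for the end-to-end comparison; every CLI flag of
#' the bundled `dxrank` script has a counterpart here.
#'
#' @param seed Master seed for the run.
#' @param design Study design (`dx_design`).
#' @param params Generator parameters (`dx_params`).
#' @param backends Backend labels to impute with.
#' @param modes Imputation modes to run.
#' @param coding Coding for the SNR ranking.
#' @param n_iter,burn_in MCMC settings for the Bayesian module.
#' @param loo_max_n Per-step LOO evaluation cap (see [loo_accuracy()]).
#' @param run_bayes,run_validation Toggle the slower stages.
#' @return A list of class `dx_config`.
#' @export
pipeline_config <- function(seed = 1L, design = canonical_design(),
                            params = generator_params(),
                            backends = c("3nn", "5nn", "10nn", "mlr", "mlp"),
                            modes = c("supervised", "unsupervised"),
                            coding = "multilevel",
                            n_iter = 2000L, burn_in = 500L,
                            loo_max_n = 150L,
                            run_bayes = TRUE, run_validation = TRUE) {
  structure(list(seed = as.integer(seed), design = design, params = params,
                 backends = backends, modes = modes, coding = coding,
                 n_iter = n_iter, burn_in = burn_in, loo_max_n = loo_max_n,
                 run_bayes = isTRUE(run_bayes),
                 run_validation = isTRUE(run_validation)),
            class = "dx_config")
}

write_table <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  df
}

#' Run the end-to-end comparison pipeline
#'
#' Executes generate, integrate, SNR ranking, measured accuracy, imputation
#' under every requested backend and mode, post-imputation ranking and
#' accuracy, imputation validation, and the Bayesian accuracy model, and
#' assembles the three-criteria comparison report (SNR, sensitivity,
#' specificity per test and data condition). When `out_dir` is given every
#' intermediate table is written there (`cohort.csv`, `integrated.csv`,
#' `audit.json`, `snr.csv`, `accuracy.csv`, `imputed_<backend>_<mode>.csv`,
#' `validation.csv`, `bayes_accuracy.csv`, `report.csv`, `scatter.csv`,
#' `run.log`).
#'
#' @param config A `dx_config` from [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `report` (per test x condition: snr, sens, spec, CIs,
#'   snr_rank), `scatter` (the sensitivity/specificity point table with the
#'   per-condition separation statistic), `accuracy`, `validation`, `bayes`,
#'   `audit` and `impute_logs`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "dx_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- c(sprintf("seed: %d", config$seed))
  cohort <- generate_cohort(config$design, config$params, seed = config$seed)
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  ds <- integrate_cohort(cohort)
  audit <- attr(ds, "audit")
  if (!is.null(out_dir)) {
    write_cohort(ds, file.path(out_dir, "integrated.csv"))
    jsonlite::write_json(audit, file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  log_lines <- c(log_lines,
                 sprintf("integrated: %d retained of %d", audit$retained_n,
                         audit$input_n))

  conditions <- list(measured = ds)
  plan <- canonical_plan()
  impute_logs <- list()
  for (b in config$backends) {
    for (mode in config$modes) {
      backend <- parse_backend(b, supervised = mode == "supervised",
                               seed = config$seed)
      label <- sprintf("%s_%s", b, mode)
      imp <- withCallingHandlers(
        run_plan(ds, plan, backend),
        warning = function(w) {
          log_lines <<- c(log_lines, sprintf("[%s] warning: %s", label,
                                             conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      conditions[[label]] <- imp
      impute_logs[[label]] <- attr(imp, "impute_log")
      log_lines <- c(log_lines, sprintf(
        "[%s] imputed %d cell(s); min measured fraction %.2f", label,
        sum(attr(imp, "impute_log")$n_imputed),
        min(attr(imp, "impute_log")$measured_fraction)))
      if (!is.null(out_dir)) {
        write_cohort(imp, file.path(out_dir,
                                    sprintf("imputed_%s_%s.csv", b, mode)))
      }
    }
  }

  snr_tables <- lapply(names(conditions), function(cond) {
    r <- rank_tests(conditions[[cond]], coding = config$coding)
    r$condition <- cond
    r
  })
  snr_all <- do.call(rbind, snr_tables)
  write_table(snr_all, out_dir, "snr.csv")

  acc_tables <- lapply(names(conditions), function(cond) {
    scope <- if (cond == "measured") "measured_only" else "imputed_full"
    a <- test_accuracy(conditions[[cond]], scope = scope)
    a$condition <- cond
    a
  })
  acc_all <- do.call(rbind, acc_tables)
  write_table(acc_all, out_dir, "accuracy.csv")

  validation <- NULL
  if (config$run_validation) {
    validation <- validate_imputation(ds, backends = config$backends,
                                      modes = config$modes, plan = plan,
                                      seed = config$seed,
                                      loo_max_n = config$loo_max_n)
    write_table(validation$report, out_dir, "validation.csv")
    log_lines <- c(log_lines,
                   sprintf("best imputation method: %s %s",
                           validation$best$backend, validation$best$mode))
  }

  bayes <- NULL
  if (config$run_bayes) {
    bayes <- bayes_accuracy(ds, n_iter = config$n_iter,
                            burn_in = config$burn_in, seed = config$seed)
    write_table(bayes, out_dir, "bayes_accuracy.csv")
  }

  report <- merge(
    snr_all[snr_all$variable %in% DX_TESTS,
            c("condition", "variable", "snr", "rank")],
    acc_all[, c("condition", "test", "sens", "sens_lo", "sens_hi",
                "spec", "spec_lo", "spec_hi")],
    by.x = c("condition", "variable"), by.y = c("condition", "test"))
  names(report)[names(report) == "variable"] <- "test"
  names(report)[names(report) == "rank"] <- "snr_rank"
  report <- report[order(report$condition, report$snr_rank), ]
  rownames(report) <- NULL
  write_table(report, out_dir, "report.csv")

  scatter <- scatter_table(report)
  write_table(scatter$points, out_dir, "scatter.csv")

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(report = report, scatter = scatter, accuracy = acc_all,
       snr = snr_all, validation = validation, bayes = bayes, audit = audit,
       impute_logs = impute_logs)
}

#' Sensitivity-specificity scatter table and cluster separation
#'
#' Projects the comparison report to one (sensitivity, specificity) point
#' per test and condition — the data behind a two-dimensional comparison
#' plot — and computes a per-condition separation statistic: the Euclidean
#' distance (in percentage-point units) between Cxbladder Detect's point
#' and the centroid of the other three tests' points. Identical points give
#' a separation of 0.
#'
#' @param report Report data frame from [run_pipeline()] (columns
#'   `condition`, `test`, `sens`, `spec`).
#' @return List with `points` (condition, test, sens, spec) and
#'   `separation` (condition, cxbladder_gap).
#' @export
scatter_table <- function(report) {
  points <- report[, c("condition", "test", "sens", "spec")]
  separation <- do.call(rbind, lapply(split(points, points$condition),
                                      function(p) {
    cx <- p[p$test == "cxbladder", ]
    rest <- p[p$test != "cxbladder", ]
    gap <- if (nrow(cx) == 1L && nrow(rest) > 0L) {
      sqrt((cx$sens - mean(rest$sens))^2 + (cx$spec - mean(rest$spec))^2)
    } else NA_real_
    data.frame(condition = p$condition[1L], cxbladder_gap = gap,
               stringsAsFactors = FALSE)
  }))
  rownames(separation) <- NULL
  list(points = points, separation = separation)
}
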