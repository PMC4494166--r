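## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so seeded helpers compose predictably.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' The canonical five-study design
#'
#' Blueprint of the five contributing urothelial-carcinoma studies: original
#' sample sizes, analyzed UC / non-UC counts (records surviving integration),
#' which of the four tests each study measured, additional individually
#' missing cells among otherwise-measured tests, and the number of invalid
#' records (no cystoscopy truth, or a single test result) that integration
#' discards. Datasets 1-3 are primary-detection (hematuria) cohorts;
#' Datasets 4-5 are post-treatment surveillance cohorts. Only Dataset 5
#' measured all four tests, with 2 NMP22 and 3 cytology cells individually
#' missing.
#'
#' @return An object of class `dx_design`: a list with a `datasets` data
#'   frame (`dataset_id`, `original_n`, `analyzed_uc`, `analyzed_nonuc`,
#'   `invalid_records`, `setting`), a `measured_tests` list and an
#'   `individual_missing` list, both keyed by dataset.
#' @examples
#' d <- canonical_design()
#' sum(d$datasets$original_n)   # 978
#' sum(d$datasets$analyzed_uc)  # 89
#' @export
canonical_design <- function() {
  datasets <- data.frame(
    dataset_id     = 1:5,
    original_n     = c(476L, 94L, 84L, 200L, 124L),
    analyzed_uc    = c(63L, 6L, 5L, 6L, 9L),
    analyzed_nonuc = c(411L, 74L, 63L, 187L, 115L),
    setting        = c("primary", "primary", "primary",
                       "surveillance", "surveillance"),
    stringsAsFactors = FALSE
  )
  datasets$invalid_records <- datasets$original_n -
    datasets$analyzed_uc - datasets$analyzed_nonuc
  design <- list(
    datasets = datasets,
    measured_tests = list(
      `1` = c("cytology", "nmp22", "cxbladder"),
      `2` = c("cytology", "cxbladder"),
      `3` = c("cytology", "cxbladder"),
      `4` = c("cytology", "nmp22", "fish"),
      `5` = c("cytology", "nmp22", "fish", "cxbladder")
    ),
    individual_missing = list(
      `1` = c(), `2` = c(), `3` = c(), `4` = c(),
      `5` = c(nmp22 = 2L, cytology = 3L)
    )
  )
  class(design) <- "dx_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  ds <- design$datasets
  bad <- ds$analyzed_uc + ds$analyzed_nonuc + ds$invalid_records != ds$original_n
  if (any(bad)) {
    stop(sprintf("design invariant violated: analyzed + invalid != original_n for dataset(s) %s",
                 paste(ds$dataset_id[bad], collapse = ", ")), call. = FALSE)
  }
  if (any(ds$invalid_records < 0)) {
    stop("design invariant violated: negative invalid_records", call. = FALSE)
  }
  for (d in ds$dataset_id) {
    im <- design$individual_missing[[as.character(d)]]
    extra <- setdiff(names(im), design$measured_tests[[as.character(d)]])
    if (length(extra) > 0L) {
      stop(sprintf("dataset %d: individual_missing names unmeasured test(s) %s",
                   d, paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(design)
}

#' @export
print.dx_design <- function(x, ...) {
  cat("Multi-study diagnostic design:", nrow(x$datasets), "datasets,",
      sum(x$datasets$original_n), "original records,",
      sum(x$datasets$analyzed_uc), "UC /",
      sum(x$datasets$analyzed_nonuc), "non-UC analyzed\n")
  df <- x$datasets
  df$tests <- vapply(as.character(df$dataset_id),
                     function(d) paste(x$measured_tests[[d]], collapse = "+"),
                     character(1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Generator parameters for synthetic cohorts
#'
#' Per-test accuracy probabilities and demographic distributions used by
#' [generate_cohort()]. Defaults reproduce the measured-data accuracies of
#' the integrated urothelial-carcinoma cohort (cytology 45.5/96.3, NMP22
#' 44.9/89.0, FISH 40.0/87.3, Cxbladder Detect 79.5/82.2, as
#' sensitivity/specificity percents) together with plausible urology-clinic
#' demographics: age truncated normal (mean 65, sd 12, floor 18) and 70 %
#' male.
#'
#' @param sensitivity,specificity Named numeric vectors over the four tests,
#'   probabilities in (0,1).
#' @param p_atypical Probability that a binary-negative cytology is coded 2
#'   (atypical) rather than 1.
#' @param p_suspicious Probability that a binary-positive cytology is coded 3
#'   (suspicious) rather than 4.
#' @param age_mean,age_sd,age_floor Truncated-normal age distribution (years).
#' @param p_male Proportion of males (gender code 1).
#' @param p_other Fraction of analyzed non-UC records emitted with the
#'   distinct "other-cause" truth (e.g. kidney stones); integration
#'   reclassifies them to non-UC.
#' @param rho Optional shared latent-severity correlation knob: with
#'   `rho > 0` a per-subject standard-normal severity shifts every test's
#'   positivity on the logit scale, inducing positive dependence between
#'   tests given truth. Off (0) by default: tests are conditionally
#'   independent given truth.
#' @return A list of class `dx_params`.
#' @export
generator_params <- function(
    sensitivity = c(cytology = 0.455, nmp22 = 0.449,
                    fish = 0.400, cxbladder = 0.795),
    specificity = c(cytology = 0.963, nmp22 = 0.890,
                    fish = 0.873, cxbladder = 0.822),
    p_atypical = 0.40, p_suspicious = 0.50,
    age_mean = 65, age_sd = 12, age_floor = 18,
    p_male = 0.70, p_other = 0.10, rho = 0) {
  stopifnot(all(DX_TESTS %in% names(sensitivity)),
            all(DX_TESTS %in% names(specificity)),
            all(sensitivity > 0 & sensitivity < 1),
            all(specificity > 0 & specificity < 1),
            p_atypical >= 0, p_atypical <= 1,
            p_suspicious >= 0, p_suspicious <= 1,
            p_other >= 0, p_other <= 1, rho >= 0)
  structure(list(sensitivity = sensitivity[DX_TESTS],
                 specificity = specificity[DX_TESTS],
                 p_atypical = p_atypical, p_suspicious = p_suspicious,
                 age_mean = age_mean, age_sd = age_sd, age_floor = age_floor,
                 p_male = p_male, p_other = p_other, rho = rho),
            class = "dx_params")
}

rtruncnorm_floor <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < floor)) {
    idx <- x < floor
    x[idx] <- stats::rnorm(sum(idx), mean, sd)
  }
  x
}

## Draw coded results for one test given a latent binary disease status.
## `diseased` is logical; `severity` the optional shared latent (rho knob).
draw_test_codes <- function(test, diseased, params, severity) {
  p <- ifelse(diseased, params$sensitivity[[test]],
              1 - params$specificity[[test]])
  if (params$rho > 0) {
    p <- stats::plogis(stats::qlogis(p) + params$rho * severity)
  }
  pos <- stats::runif(length(p)) < p
  if (test == "cytology") {
    code <- ifelse(pos,
                   ifelse(stats::runif(length(p)) < params$p_suspicious, 3L, 4L),
                   ifelse(stats::runif(length(p)) < params$p_atypical, 2L, 1L))
  } else {
    code <- ifelse(pos, 2L, 1L)
  }
  as.integer(code)
}

#' Generate a seeded synthetic multi-study cohort
#'
#' Emits exactly `original_n` subject records per dataset following the
#' design: analyzed subjects carry UC or non-UC truth in the design's
#' proportions (a configurable fraction of non-UC emitted as "other-cause");
#' every test measured by the subject's study is drawn positive with
#' probability `sensitivity` (UC) or `1 - specificity` (non-UC), then coded;
#' individually missing cells are blanked uniformly at random among the
#' dataset's analyzed records; and the design's invalid records are emitted
#' as unknown-truth records or single-test records (split half and half) so
#' that integration discards them.
#'
#' @param design A `dx_design`, e.g. [canonical_design()].
#' @param params A `dx_params`, e.g. [generator_params()].
#' @param seed Integer seed; fully determines the output.
#' @return Cohort data frame (see [read_cohort()] for the schema).
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)  # 978
#' @export
generate_cohort <- function(design = canonical_design(),
                            params = generator_params(), seed = 1L) {
  validate_design(design)
  with_seed(seed, {
    out <- lapply(design$datasets$dataset_id, function(d) {
      row <- design$datasets[design$datasets$dataset_id == d, ]
      tests <- design$measured_tests[[as.character(d)]]
      n_uc <- row$analyzed_uc
      n_other <- round(params$p_other * row$analyzed_nonuc)
      n_nonuc <- row$analyzed_nonuc - n_other
      n_inv <- row$invalid_records
      n_notruth <- n_inv %/% 2L
      n_single <- n_inv - n_notruth
      n <- row$original_n

      truth <- c(rep("UC", n_uc), rep("nonUC", n_nonuc),
                 rep("other", n_other), rep("unknown", n_notruth),
                 rep("nonUC", n_single))
      diseased <- truth == "UC"  # unknown-truth records drawn as non-UC
      severity <- stats::rnorm(n)

      rec <- data.frame(
        subject_id = sprintf("D%d-%04d", d, seq_len(n)),
        dataset_id = d,
        age = round(rtruncnorm_floor(n, params$age_mean, params$age_sd,
                                     params$age_floor), 1),
        gender = ifelse(stats::runif(n) < params$p_male, 1L, 2L),
        truth = truth,
        cytology = NA_integer_, nmp22 = NA_integer_,
        fish = NA_integer_, cxbladder = NA_integer_,
        stringsAsFactors = FALSE
      )
      for (t in tests) {
        rec[[t]] <- draw_test_codes(t, diseased, params, severity)
      }

      ## Individually missing cells fall in distinct analyzed records so a
      ## subject never loses two tests at once (keeps every record at >= 2
      ## tests and every imputation step's inputs complete).
      analyzed <- seq_len(n_uc + n_nonuc + n_other)
      im <- design$individual_missing[[as.character(d)]]
      blanked <- integer()
      for (t in names(im)) {
        eligible <- setdiff(analyzed[!is.na(rec[[t]][analyzed])], blanked)
        blank <- sample(eligible, im[[t]])
        rec[[t]][blank] <- NA_integer_
        blanked <- c(blanked, blank)
      }

      if (n_single > 0L) {
        single <- (n - n_single + 1L):n
        for (i in single) {
          keep <- sample(tests, 1L)
          rec[i, setdiff(tests, keep)] <- NA_integer_
        }
      }
      rec
    })
    records <- do.call(rbind, out)
    rownames(records) <- NULL
    ensure_provenance(records)
  })
}
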