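#' @keywords internal
"_PACKAGE"

## The four urine-based tests compared against the cystoscopy gold standard.
## Cytology is reported on a 4-level code; the molecular tests are binary.
DX_TESTS <- c("cytology", "nmp22", "fish", "cxbladder")

DX_ALPHABETS <- list(
  cytology  = 1:4,  # 1 negative, 2 atypical, 3 suspicious, 4 positive
  nmp22     = 1:2,  # 1 negative (<10 U), 2 positive
  fish      = 1:2,
  cxbladder = 1:2   # 1 "Low", 2 "Elevated"/"High"
)

DX_TRUTH_LEVELS <- c("UC", "nonUC", "other", "unknown")
DX_PROVENANCE   <- c("measured", "imputed", "missing")

src_col <- function(test) paste0(test, "_src")

#' Collapse a coded test result to a binary outcome
#'
#' All four tests are analysed as binary calls for urothelial carcinoma (UC).
#' Cytology codes 1 (negative) and 2 (atypical) collapse to `"negative"`,
#' codes 3 (suspicious) and 4 (positive) to `"positive"`. For NMP22, FISH and
#' Cxbladder Detect, code 1 is `"negative"` and code 2 `"positive"`.
#'
#' @param test_kind One of `"cytology"`, `"nmp22"`, `"fish"`, `"cxbladder"`.
#' @param code Integer vector of coded results; `NA` allowed (returned as
#'   `NA`).
#' @return Character vector in `{"positive", "negative", NA}`.
#' @examples
#' to_binary("cytology", c(1, 2, 3, 4))
#' to_binary("nmp22", 2)
#' @export
to_binary <- function(test_kind, code) {
  test_kind <- match.arg(test_kind, DX_TESTS)
  alphabet <- DX_ALPHABETS[[test_kind]]
  bad <- !is.na(code) & !(code %in% alphabet)
  if (any(bad)) {
    stop(sprintf("invalid %s code(s): %s (alphabet: %s)",
                 test_kind, paste(unique(code[bad]), collapse = ", "),
                 paste(alphabet, collapse = ",")), call. = FALSE)
  }
  threshold <- if (test_kind == "cytology") 2L else 1L
  out <- ifelse(code > threshold, "positive", "negative")
  out[is.na(code)] <- NA_character_
  out
}

## TRUE where a coded result is a positive UC call; NA propagates.
binary_positive <- function(test_kind, code) {
  b <- to_binary(test_kind, code)
  ifelse(is.na(b), NA, b == "positive")
}

#' Validate subject records against the cohort schema
#'
#' Checks every record of a cohort data frame against the domain invariants:
#' codes inside each test's alphabet, age positive and never missing, gender
#' coded 1 (male) or 2 (female), truth one of `UC|nonUC|other|unknown`,
#' dataset id in 1..5, and provenance flags consistent with the cells they
#' annotate (a non-missing cell is `measured` or `imputed`; a missing cell is
#' `missing`).
#'
#' @param records Cohort data frame (see [read_cohort()] for the schema).
#' @return A data frame of violations with columns `row`, `field`, `reason`;
#'   zero rows when every invariant holds.
#' @export
validate_record <- function(records) {
  stopifnot(is.data.frame(records))
  v <- list()
  flag <- function(rows, field, reason) {
    if (any(rows)) {
      v[[length(v) + 1L]] <<- data.frame(
        row = which(rows), field = field, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  flag(is.na(records$age) | records$age <= 0, "age",
       "age must be a positive number and is never missing")
  flag(is.na(records$gender) | !(records$gender %in% 1:2), "gender",
       "gender must be coded 1 (male) or 2 (female) and is never missing")
  flag(!(records$truth %in% DX_TRUTH_LEVELS), "truth",
       sprintf("truth must be one of %s",
               paste(DX_TRUTH_LEVELS, collapse = "|")))
  flag(is.na(records$dataset_id) | !(records$dataset_id %in% 1:5),
       "dataset_id", "dataset_id must be an integer in 1..5")
  for (t in DX_TESTS) {
    code <- records[[t]]
    flag(!is.na(code) & !(code %in% DX_ALPHABETS[[t]]), t,
         sprintf("code outside alphabet {%s}",
                 paste(DX_ALPHABETS[[t]], collapse = ",")))
    sc <- src_col(t)
    if (sc %in% names(records)) {
      prov <- records[[sc]]
      flag(!(prov %in% DX_PROVENANCE), sc,
           "provenance must be measured|imputed|missing")
      flag(!is.na(code) & prov == "missing", sc,
           "non-missing cell flagged as provenance missing")
      flag(is.na(code) & prov != "missing", sc,
           "missing cell must have provenance missing")
    }
  }
  if (length(v) == 0L) {
    data.frame(row = integer(), field = character(), reason = character(),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, v)
    out[order(out$row, out$field), , drop = FALSE]
  }
}

## Ensure the four provenance sidecar columns exist and are consistent:
## cells present in the data but without a flag default to "measured".
ensure_provenance <- function(records) {
  for (t in DX_TESTS) {
    sc <- src_col(t)
    if (!sc %in% names(records) || all(is.na(records[[sc]]))) {
      records[[sc]] <- ifelse(is.na(records[[t]]), "missing", "measured")
    }
  }
  records
}

#' Read a cohort CSV
#'
#' The schema has one header row:
#' `subject_id,dataset_id,age,gender,truth,cytology,nmp22,fish,cxbladder`
#' plus optional provenance sidecars `cytology_src,...,cxbladder_src`.
#' Missing test cells are empty fields. When sidecars are absent every
#' present cell is taken as `measured`.
#'
#' @param path Path to the CSV file.
#' @param validate Raise an error on invariant violations (default `TRUE`).
#' @return Cohort data frame.
#' @export
read_cohort <- function(path, validate = TRUE) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(subject_id = "character"))
  for (col in c("dataset_id", "gender", DX_TESTS)) {
    records[[col]] <- as.integer(records[[col]])
  }
  records <- ensure_provenance(records)
  if (validate) {
    bad <- validate_record(records)
    if (nrow(bad) > 0L) {
      stop(sprintf("cohort fails validation (%d violation(s)); first: row %d, %s: %s",
                   nrow(bad), bad$row[1], bad$field[1], bad$reason[1]),
           call. = FALSE)
    }
  }
  records
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing cells serialize as empty fields and
#' provenance flags go to the `*_src` sidecar columns, so a round trip
#' preserves every field bit-exactly.
#'
#' @param records Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- ensure_provenance(records)
  cols <- c("subject_id", "dataset_id", "age", "gender", "truth",
            DX_TESTS, src_col(DX_TESTS))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
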