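#' Case-level cohort tables
#'
#' A cohort is an ordinary tibble with one row per published case report and a
#' fixed column schema: identification (`case_id`, `citation`), demographics
#' (`age_years`, `sex`), exposure (`exposure_type`, `substance`, `dose_g`,
#' `serum_ng_ml`, `co_ingestants`), the arrhythmia outcome (`vt_vf`), and the
#' admission-ECG intervals (`qrs_ms`, `qt_ms`, `qtc_ms`, `hr_bpm`). Doses and
#' serum concentrations missing from the source reports are `NA`, never zero.
#' `co_ingestants` is a semicolon-separated string, `""` when none were taken.
#'
#' @name cohort
#' @keywords internal
NULL

cohort_columns <- c(
  "case_id", "citation", "age_years", "sex", "exposure_type", "substance",
  "dose_g", "serum_ng_ml", "co_ingestants", "vt_vf",
  "qrs_ms", "qt_ms", "qtc_ms", "hr_bpm"
)

cohort_col_types <- readr::cols(
  case_id = readr::col_integer(),
  citation = readr::col_character(),
  age_years = readr::col_double(),
  sex = readr::col_character(),
  exposure_type = readr::col_character(),
  substance = readr::col_character(),
  dose_g = readr::col_double(),
  serum_ng_ml = readr::col_double(),
  co_ingestants = readr::col_character(),
  vt_vf = readr::col_logical(),
  qrs_ms = readr::col_double(),
  qt_ms = readr::col_double(),
  qtc_ms = readr::col_double(),
  hr_bpm = readr::col_double()
)

#' Load a case-level cohort
#'
#' Reads a cohort from CSV or JSON, or returns the packaged 16-case cohort of
#' citalopram/escitalopram case reports with admission-ECG intervals. The
#' packaged cohort is the complete published dataset: 11 female and 5 male
#' patients, 12 intoxications and 4 therapeutic-dose exposures, of whom 7
#' developed ventricular tachycardia or fibrillation after the admission ECG.
#'
#' @param source `"packaged"` (default) for the bundled case-report cohort, or
#'   a path to a `.csv` or `.json` file following the cohort schema.
#' @param format File format, normally inferred from the extension.
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @examples
#' cohort <- load_cohort()
#' nrow(cohort)            # 16
#' sum(cohort$vt_vf)       # 7
#' @export
load_cohort <- function(source = "packaged", format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (identical(source, "packaged")) {
    source <- system.file("extdata", "citalopram_cohort.csv", package = "qrsqtc",
                          mustWork = TRUE)
    format <- "csv"
  }
  if (!file.exists(source)) {
    qrsqtc_abort(paste0("cohort file does not exist: ", source), "qrsqtc_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  x <- if (format == "csv") read_cohort_csv(source) else read_cohort_json(source)
  validate_cohort(x)
}

read_cohort_csv <- function(path) {
  header <- names(suppressWarnings(suppressMessages(
    readr::read_csv(path, n_max = 0, show_col_types = FALSE)
  )))
  missing_cols <- setdiff(cohort_columns, header)
  if (length(missing_cols) > 0) {
    qrsqtc_abort(
      paste0("cohort file is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "qrsqtc_schema_error"
    )
  }
  x <- readr::read_csv(path, col_types = cohort_col_types, progress = FALSE)
  x$co_ingestants[is.na(x$co_ingestants)] <- ""
  tibble::as_tibble(x[cohort_columns])
}

read_cohort_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(raw) == 0 || !is.data.frame(raw)) {
    qrsqtc_abort("JSON cohort must be a non-empty array of case objects",
                 "qrsqtc_schema_error")
  }
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    qrsqtc_abort(
      paste0("cohort file is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "qrsqtc_schema_error"
    )
  }
  x <- tibble::as_tibble(raw[cohort_columns])
  x$case_id <- as.integer(x$case_id)
  for (col in c("age_years", "dose_g", "serum_ng_ml",
                "qrs_ms", "qt_ms", "qtc_ms", "hr_bpm")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x$vt_vf <- as.logical(x$vt_vf)
  x$co_ingestants[is.na(x$co_ingestants)] <- ""
  x
}

#' Validate a cohort table
#'
#' Checks the schema and the physiological range invariants: ages in
#' \[0, 130\]; positive doses and serum concentrations where present; QRS in
#' \[40, 300\] ms; QT and QTc in \[200, 800\] ms; heart rate in \[20, 250\]
#' bpm; QRS strictly shorter than QT; unique case identifiers. Errors name the
#' offending case and field.
#'
#' @param cohort A cohort tibble.
#' @return The cohort, invisibly unchanged, as a tibble.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    qrsqtc_abort(
      paste0("cohort is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "qrsqtc_schema_error"
    )
  }
  if (nrow(cohort) == 0) {
    qrsqtc_abort("cohort has no records", "qrsqtc_schema_error")
  }
  if (anyDuplicated(cohort$case_id)) {
    qrsqtc_abort("case_id values must be unique", "qrsqtc_validation_error")
  }
  check_range <- function(field, lo, hi, required = TRUE, strict_lo = FALSE) {
    v <- cohort[[field]]
    if (required && anyNA(v)) {
      bad <- cohort$case_id[is.na(v)]
      qrsqtc_abort(paste0("case ", bad[1], ": field '", field, "' is missing"),
                   "qrsqtc_validation_error")
    }
    ok <- is.na(v) | (if (strict_lo) v > lo else v >= lo) & v <= hi
    if (!all(ok)) {
      bad <- cohort$case_id[!ok][1]
      qrsqtc_abort(
        paste0("case ", bad, ": field '", field, "' out of range [",
               lo, ", ", hi, "]"),
        "qrsqtc_validation_error"
      )
    }
  }
  check_range("age_years", 0, 130)
  check_range("dose_g", 0, Inf, required = FALSE, strict_lo = TRUE)
  check_range("serum_ng_ml", 0, Inf, required = FALSE, strict_lo = TRUE)
  check_range("qrs_ms", 40, 300)
  check_range("qt_ms", 200, 800)
  check_range("qtc_ms", 200, 800)
  check_range("hr_bpm", 20, 250)
  for (field in c("sex", "exposure_type", "substance", "vt_vf")) {
    if (anyNA(cohort[[field]])) {
      bad <- cohort$case_id[is.na(cohort[[field]])][1]
      qrsqtc_abort(paste0("case ", bad, ": field '", field, "' is missing"),
                   "qrsqtc_validation_error")
    }
  }
  check_level <- function(field, levels) {
    ok <- cohort[[field]] %in% levels
    if (!all(ok)) {
      bad <- cohort$case_id[!ok][1]
      qrsqtc_abort(
        paste0("case ", bad, ": field '", field, "' must be one of ",
               paste(levels, collapse = ", ")),
        "qrsqtc_validation_error"
      )
    }
  }
  check_level("sex", c("F", "M"))
  check_level("exposure_type", c("intoxication", "therapeutic"))
  check_level("substance", c("citalopram", "escitalopram"))
  narrow <- cohort$qrs_ms >= cohort$qt_ms
  if (any(narrow)) {
    bad <- cohort$case_id[narrow][1]
    qrsqtc_abort(
      paste0("case ", bad, ": qrs_ms must be strictly less than qt_ms"),
      "qrsqtc_validation_error"
    )
  }
  tibble::as_tibble(cohort)
}

#' Write a cohort to CSV or JSON
#'
#' Round-trip safe: [load_cohort()] on the written file reproduces the cohort
#' field for field, including half-millisecond QRS values and missingness
#' (empty CSV cells / JSON `null`, never 0).
#'
#' @param cohort A validated cohort tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  cohort <- validate_cohort(cohort)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    out <- cohort
    out$vt_vf <- tolower(as.character(out$vt_vf))
    readr::write_csv(out, path, na = "")
  } else {
    jsonlite::write_json(cohort, path, na = "null", auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Filter a cohort by case-level predicates
#'
#' A thin wrapper around [dplyr::filter()] that preserves case order and the
#' cohort schema. Unlike the analysis functions, an empty result is allowed.
#'
#' @param cohort A cohort tibble.
#' @param ... Logical predicates on cohort columns, as in [dplyr::filter()].
#' @return The matching sub-cohort (possibly zero rows).
#' @examples
#' cohort <- load_cohort()
#' nrow(filter_cohort(cohort, vt_vf))                    # 7
#' nrow(filter_cohort(cohort, substance == "escitalopram")) # 3
#' @export
filter_cohort <- function(cohort, ...) {
  dplyr::filter(cohort, ...)
}

#' QRS/QTc ratios of a cohort
#'
#' Computes the QRS/QTc column for a cohort. With `digits = 2` (the default)
#' the ratio is rounded half-up to two decimals, matching the published
#' tabulation; `digits = NULL` returns full precision, the convention used for
#' synthetic cohorts.
#'
#' @param cohort A cohort tibble.
#' @param digits Decimal places for [round_half_up()], or `NULL` for full
#'   precision.
#' @return Numeric vector of ratios, one per case.
#' @export
cohort_ratio <- function(cohort, digits = 2) {
  qrs_qtc_ratio(cohort$qrs_ms, cohort$qtc_ms, digits = digits)
}

#' @rdname cohort_ratio
#' @return `add_ratio()` returns the cohort with a `ratio` column appended.
#' @export
add_ratio <- function(cohort, digits = 2) {
  dplyr::mutate(cohort, ratio = cohort_ratio(cohort, digits = digits))
}
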