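#' EMR dataset container
#'
#' Bundle the relational tables of a CPCSSN-style primary care EMR extract
#' into a single validated object.  The extract comprises a patient table,
#' coded diagnoses drawn from three source tables (health condition, billing,
#' encounter diagnosis), a medication table with ATC codes, and optionally a
#' table of chart-review reference labels.
#'
#' @param patients Data frame with columns `patient_id`, `birth_year`, `sex`,
#'   `region`, `last_encounter_date`.
#' @param coded Data frame with columns `patient_id`, `source` (one of
#'   `"health_condition"`, `"billing"`, `"encounter_diagnosis"`), `code`
#'   (ICD-9-CM string), `date`, and optionally `diagnosis_text` (the short
#'   provider-entered diagnosis name / reason for encounter).
#' @param medications Data frame with columns `patient_id`, `atc_code`,
#'   `date`, or `NULL` for none.
#' @param labels Optional data frame with columns `patient_id`, `label`
#'   (`"PTSD"`, `"no_PTSD"` or `"possible_PTSD"`) and `source`.
#'
#' @return An object of class `emr_dataset`: a list of tibbles
#'   `patients`, `coded`, `medications`, `labels`.
#'
#' @details Validation enforces the column schema, the three-way `source`
#'   enumeration, non-empty codes, parseable dates, uniqueness of
#'   `patient_id` in the patient table, and referential integrity: every
#'   coded or medication row must reference a patient present in `patients`.
#'
#' @examples
#' ds <- emr_dataset(
#'   patients = data.frame(
#'     patient_id = "p1", birth_year = 1980L, sex = "F", region = "MB",
#'     last_encounter_date = "2019-06-01"
#'   ),
#'   coded = data.frame(
#'     patient_id = "p1", source = "billing", code = "309.81",
#'     date = "2019-06-01", diagnosis_text = "PTSD"
#'   )
#' )
#' ds
#' @export
emr_dataset <- function(patients, coded, medications = NULL, labels = NULL) {
  patients <- check_table(patients, "patient",
    c("patient_id", "birth_year", "sex", "region", "last_encounter_date"))
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop("duplicate patient_id in patient table: ",
      paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  patients$birth_year <- as.integer(patients$birth_year)
  patients$last_encounter_date <- parse_emr_date(patients$last_encounter_date,
    required = FALSE)

  coded <- check_table(coded, "coded diagnosis",
    c("patient_id", "source", "code", "date"))
  if (!"diagnosis_text" %in% names(coded)) coded$diagnosis_text <- NA_character_
  coded$diagnosis_text <- as.character(coded$diagnosis_text)
  bad_src <- setdiff(unique(coded$source), coded_sources())
  if (length(bad_src)) {
    stop("unknown coded-record source(s): ", paste(bad_src, collapse = ", "),
      "; expected ", paste(coded_sources(), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(coded$code) | !nzchar(trimws(coded$code)))) {
    stop("coded records must carry a non-empty ICD-9-CM code", call. = FALSE)
  }
  coded$code <- as.character(coded$code)
  coded$date <- parse_emr_date(coded$date)

  if (is.null(medications)) {
    medications <- tibble::tibble(patient_id = character(),
      atc_code = character(), date = as.Date(character()))
  }
  medications <- check_table(medications, "medication",
    c("patient_id", "atc_code", "date"))
  medications$atc_code <- as.character(medications$atc_code)
  medications$date <- parse_emr_date(medications$date)

  if (!is.null(labels)) {
    labels <- check_table(labels, "labels", c("patient_id", "label", "source"))
    bad_lab <- setdiff(unique(labels$label), label_levels())
    if (length(bad_lab)) {
      stop("unknown reference label(s): ", paste(bad_lab, collapse = ", "),
        call. = FALSE)
    }
    if (anyDuplicated(labels[c("patient_id", "source")])) {
      stop("labels must contain one final label per patient per source",
        call. = FALSE)
    }
  }

  check_orphans(coded$patient_id, patients$patient_id, "coded diagnosis")
  check_orphans(medications$patient_id, patients$patient_id, "medication")

  structure(
    list(patients = tibble::as_tibble(patients),
         coded = tibble::as_tibble(coded),
         medications = tibble::as_tibble(medications),
         labels = if (is.null(labels)) NULL else tibble::as_tibble(labels)),
    class = "emr_dataset"
  )
}

coded_sources <- function() c("health_condition", "billing", "encounter_diagnosis")
label_levels <- function() c("PTSD", "no_PTSD", "possible_PTSD")

check_table <- function(x, what, required) {
  if (!is.data.frame(x)) stop(what, " table must be a data frame", call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("schema error: ", what, " table is missing required column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$patient_id <- as.character(x$patient_id)
  x
}

check_orphans <- function(ids, known, what) {
  orphan <- setdiff(unique(ids), known)
  if (length(orphan)) {
    stop("integrity error: ", what, " rows reference unknown patient_id(s): ",
      paste(head(orphan, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

parse_emr_date <- function(x, required = TRUE) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(x) & nzchar(trimws(as.character(x)))
  if (any(bad)) {
    stop("unparseable date value(s): ",
      paste(head(unique(x[bad]), 5), collapse = ", "),
      " (expected ISO-8601 yyyy-mm-dd)", call. = FALSE)
  }
  if (required && anyNA(out)) {
    stop("missing date value(s) where a date is required", call. = FALSE)
  }
  out
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat("<emr_dataset>\n")
  cat("  patients:    ", nrow(x$patients), "\n")
  tab <- table(factor(x$coded$source, levels = coded_sources()))
  cat("  coded rows:  ", nrow(x$coded),
      sprintf(" (health_condition %d, billing %d, encounter_diagnosis %d)",
              tab[[1]], tab[[2]], tab[[3]]), "\n")
  cat("  medications: ", nrow(x$medications), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:      ", nrow(x$labels), "\n")
  }
  invisible(x)
}

#' Read and write an EMR dataset as delimited tables
#'
#' `read_emr_dataset()` loads the five-table extract (plus an optional labels
#' table) from a directory of UTF-8 CSV files named `patient.csv`,
#' `health_condition.csv`, `billing.csv`, `encounter_diagnosis.csv`,
#' `medication.csv` and optionally `labels.csv`; `write_emr_dataset()` is its
#' inverse.  The three diagnosis tables share the schema
#' `patient_id,code,date,diagnosis_text` and are bound into one coded-record
#' table tagged by source.
#'
#' @param dir Directory containing (or to receive) the CSV files.
#' @return `read_emr_dataset()` returns an [emr_dataset]; `write_emr_dataset()`
#'   returns `dir` invisibly.
#' @seealso [emr_dataset()] for the validation rules applied on read.
#' @export
read_emr_dataset <- function(dir) {
  path <- function(f) file.path(dir, f)
  must_exist <- c("patient.csv", "health_condition.csv", "billing.csv",
    "encounter_diagnosis.csv", "medication.csv")
  absent <- must_exist[!file.exists(path(must_exist))]
  if (length(absent)) {
    stop("missing table file(s) in ", dir, ": ",
      paste(absent, collapse = ", "), call. = FALSE)
  }
  read_csv_chr <- function(f) {
    readr::read_csv(path(f), col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE)
  }
  patients <- read_csv_chr("patient.csv")
  coded <- dplyr::bind_rows(lapply(coded_sources(), function(src) {
    tab <- read_csv_chr(paste0(src, ".csv"))
    missing <- setdiff(c("patient_id", "code", "date"), names(tab))
    if (length(missing)) {
      stop("schema error: ", src, " table is missing required column(s): ",
        paste(missing, collapse = ", "), call. = FALSE)
    }
    tab$source <- src
    tab
  }))
  if (!"diagnosis_text" %in% names(coded)) coded$diagnosis_text <- NA_character_
  coded <- coded[, c("patient_id", "source", "code", "date", "diagnosis_text")]
  medications <- read_csv_chr("medication.csv")
  labels <- if (file.exists(path("labels.csv"))) read_csv_chr("labels.csv")
  ds <- emr_dataset(patients, coded, medications, labels)
  message(sprintf("read_emr_dataset: %d patients, %d coded rows, %d medication rows%s",
    nrow(ds$patients), nrow(ds$coded), nrow(ds$medications),
    if (is.null(ds$labels)) "" else sprintf(", %d labels", nrow(ds$labels))))
  ds
}

#' @rdname read_emr_dataset
#' @param dataset An [emr_dataset].
#' @export
write_emr_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "emr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$patients, file.path(dir, "patient.csv"))
  for (src in coded_sources()) {
    tab <- dataset$coded[dataset$coded$source == src,
      c("patient_id", "code", "date", "diagnosis_text")]
    readr::write_csv(tab, file.path(dir, paste0(src, ".csv")))
  }
  readr::write_csv(dataset$medications, file.path(dir, "medication.csv"))
  if (!is.null(dataset$labels)) {
    readr::write_csv(dataset$labels, file.path(dir, "labels.csv"))
  }
  invisible(dir)
}

#' ICD-9-CM code predicates
#'
#' Helpers for matching ICD-9-CM diagnosis codes as they occur in primary
#' care EMR extracts, where the same diagnosis may be recorded dotted
#' (`"309.81"`) or undotted (`"30981"`), and some jurisdictions truncate
#' billing codes to the 3-digit stem.
#'
#' `icd_normalize()` strips whitespace and dots and upper-cases, so dotted
#' and undotted forms compare equal.  `icd_prefix_match()` tests whether a
#' code begins with a prefix after both are normalized (an empty prefix
#' matches everything, by convention).  `icd_in_range()` tests whether the
#' leading 3-digit numeric stem lies in a chapter range; V- and E-prefixed
#' codes have no numeric stem and never match.
#'
#' @param code Character vector of ICD-9-CM codes.
#' @param prefix Single prefix string.
#' @param lo,hi Integer 3-digit chapter bounds, inclusive.
#' @return `icd_normalize()` a character vector; the predicates logical
#'   vectors along `code`.
#' @examples
#' icd_prefix_match("30981", "309.81")  # TRUE: dotted/undotted equivalence
#' icd_prefix_match("309", "309.81")    # FALSE: shorter than the prefix
#' icd_in_range(c("309.81", "289.9", "V70.0"), 290, 316)
#' @export
icd_normalize <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

#' @rdname icd_normalize
#' @export
icd_prefix_match <- function(code, prefix) {
  stopifnot(length(prefix) == 1)
  startsWith(icd_normalize(code), icd_normalize(prefix))
}

#' @rdname icd_normalize
#' @export
icd_in_range <- function(code, lo, hi) {
  stopifnot(length(lo) == 1, length(hi) == 1, lo <= hi)
  norm <- icd_normalize(code)
  has_stem <- grepl("^[0-9]{3}", norm)
  stem <- rep(NA_integer_, length(norm))
  stem[has_stem] <- as.integer(substr(norm[has_stem], 1, 3))
  !is.na(stem) & stem >= lo & stem <= hi
}

#' ATC code prefix matching
#'
#' Tests whether Anatomical Therapeutic Chemical codes start with any of the
#' given prefixes (case-insensitively, whitespace ignored).  The default
#' prefixes N05 (psycholeptics) and N06 (psychoanaleptics) are the drug
#' classes used as PTSD medication proxies.
#'
#' @param atc_code Character vector of ATC codes.
#' @param prefixes Character vector of ATC prefixes.
#' @return Logical vector along `atc_code`.
#' @examples
#' atc_prefix_match(c("N05BA01", "C09AA05"), c("N05", "N06"))
#' @export
atc_prefix_match <- function(atc_code, prefixes = c("N05", "N06")) {
  norm <- toupper(gsub("[[:space:]]", "", as.character(atc_code)))
  pfx <- toupper(gsub("[[:space:]]", "", prefixes))
  hit <- rep(FALSE, length(norm))
  for (p in pfx) hit <- hit | startsWith(norm, p)
  hit
}

#' Restrict to patients active around an index date
#'
#' Returns the ids of patients whose last encounter falls within
#' `window_years` before `index_date` (both endpoints inclusive) — the
#' "active patient" concept used to define surveillance denominators in
#' practice-based research networks.
#'
#' @param dataset An [emr_dataset].
#' @param index_date Index date (`Date` or ISO-8601 string).
#' @param window_years Positive look-back window in years (fractions allowed;
#'   a year is counted as 365.25 days).
#' @return Character vector of active patient ids.  Patients with a missing
#'   last encounter date are skipped with a warning reporting how many.
#' @export
filter_active <- function(dataset, index_date, window_years = 2) {
  stopifnot(inherits(dataset, "emr_dataset"), window_years > 0)
  index_date <- parse_emr_date(index_date)
  last <- dataset$patients$last_encounter_date
  skipped <- sum(is.na(last))
  if (skipped > 0) {
    warning(skipped, " patient(s) skipped: missing last_encounter_date",
      call. = FALSE)
  }
  lower <- index_date - round(window_years * 365.25)
  keep <- !is.na(last) & last >= lower & last <= index_date
  dataset$patients$patient_id[keep]
}
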