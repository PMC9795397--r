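#' Case definition parameters
#'
#' Collects the tunable parameters of the four PTSD case definitions: the
#' specific ICD-9-CM code (default 309.81, the PTSD code), the mental
#' disorders chapter range used by the text-supplemented definition
#' (default 290-316), the minimum separation between two billing/encounter
#' diagnoses (default 7 days, i.e. "at least 1 week"), the ATC prefixes
#' treated as PTSD medication proxies (default N05, N06), and the PTSD
#' mention lexicon.
#'
#' @param specific_code ICD-9-CM code identifying PTSD.
#' @param chapter_range Integer pair: inclusive 3-digit chapter bounds.
#' @param min_separation_days Minimum days between the two coded rows of the
#'   repeated-diagnosis clause.  With the default 7 ("at least 1 week") or
#'   any value of at least 1, duplicate same-day rows never count; setting 0
#'   degenerates the clause to a pure count rule (any two rows qualify).
#' @param atc_prefixes ATC code prefixes counted as PTSD medication.
#' @param lexicon A [ptsd_lexicon] used by the text clause of case
#'   definition 4.
#' @param patient_level_text If `TRUE`, the text clause of case definition 4
#'   pairs any in-range coded row with a PTSD mention anywhere in the
#'   patient's short diagnostic text; by default (`FALSE`) the mention must
#'   sit on the same row that carries the in-range code, i.e. the code
#'   recorded for that encounter.
#' @return An object of class `definition_config`.
#' @export
definition_config <- function(specific_code = "309.81",
                              chapter_range = c(290L, 316L),
                              min_separation_days = 7L,
                              atc_prefixes = c("N05", "N06"),
                              lexicon = ptsd_lexicon(),
                              patient_level_text = FALSE) {
  stopifnot(length(specific_code) == 1, nzchar(specific_code),
    length(chapter_range) == 2, chapter_range[1] <= chapter_range[2],
    min_separation_days >= 0,
    inherits(lexicon, "ptsd_lexicon"),
    is.logical(patient_level_text), length(patient_level_text) == 1)
  structure(
    list(specific_code = specific_code,
         chapter_range = as.integer(chapter_range),
         min_separation_days = as.integer(min_separation_days),
         atc_prefixes = atc_prefixes,
         lexicon = lexicon,
         patient_level_text = patient_level_text),
    class = "definition_config"
  )
}

definition_ids <- function() c("cd1", "cd2", "cd3", "cd4")

#' Evaluate one PTSD case definition for one patient
#'
#' The four definitions are boolean rules over a patient's coded diagnoses
#' (and, for `cd3()`, medications):
#'
#' * **CD1** — at least one health condition, billing or encounter diagnosis
#'   row carrying the specific PTSD code.
#' * **CD2** — at least one *health condition* row with the specific code, OR
#'   at least two billing/encounter diagnosis rows with the specific code
#'   separated by at least `min_separation_days`.
#' * **CD3** — the CD2 clauses, OR one billing/encounter diagnosis row with
#'   the specific code together with any medication whose ATC code starts
#'   with one of the configured prefixes.
#' * **CD4** — CD1, OR any coded row in the mental disorders chapter range
#'   whose own short diagnostic text contains a PTSD mention (per the
#'   lexicon), which recovers patients coded with a truncated 3-digit stem
#'   where billing rules do not allow 5-digit codes.
#'
#' Definitions nest: every CD2 positive is CD3 positive, every CD3 positive
#' is CD1 positive, and every CD1 positive is CD4 positive.
#'
#' @param records Data frame of the patient's coded rows with columns
#'   `source`, `code`, `date` and optionally `diagnosis_text` (and
#'   `patient_id`, which must be constant).  May have zero rows.
#' @param medications Data frame of the patient's medication rows with
#'   column `atc_code` (`cd3` only).
#' @param cfg A [definition_config].
#' @return An object of class `case_definition_result`: a list with
#'   `patient_id`, `definition_id`, `positive`, and `evidence` — the records
#'   that satisfied a clause, tagged with the clause name.
#' @examples
#' cfg <- definition_config()
#' recs <- data.frame(patient_id = "p1", source = "billing",
#'   code = "309", date = as.Date("2019-01-05"), diagnosis_text = "ptsd f/u")
#' cd1(recs, cfg)$positive  # FALSE: 3-digit stem is not the specific code
#' cd4(recs, cfg)$positive  # TRUE: in-chapter code with a text mention
#' @export
cd1 <- function(records, cfg = definition_config()) {
  records <- as_patient_records(records)
  hit <- icd_normalize(records$code) == icd_normalize(cfg$specific_code)
  result(records, "cd1", any(hit),
    evidence_rows(records, hit, "specific_code_any_source"))
}

#' @rdname cd1
#' @export
cd2 <- function(records, cfg = definition_config()) {
  records <- as_patient_records(records)
  is_spec <- icd_normalize(records$code) == icd_normalize(cfg$specific_code)
  hc <- is_spec & records$source == "health_condition"
  be <- is_spec & records$source %in% c("billing", "encounter_diagnosis")
  temporal <- separated_pair(records$date[be], cfg$min_separation_days)
  ev <- rbind(
    evidence_rows(records, hc, "specific_code_health_condition"),
    if (temporal) evidence_rows(records, be, "repeated_billing_encounter")
  )
  result(records, "cd2", any(hc) || temporal, ev)
}

#' @rdname cd1
#' @export
cd3 <- function(records, medications = NULL, cfg = definition_config()) {
  records <- as_patient_records(records)
  is_spec <- icd_normalize(records$code) == icd_normalize(cfg$specific_code)
  hc <- is_spec & records$source == "health_condition"
  be <- is_spec & records$source %in% c("billing", "encounter_diagnosis")
  temporal <- separated_pair(records$date[be], cfg$min_separation_days)
  has_med <- !is.null(medications) && nrow(medications) > 0 &&
    any(atc_prefix_match(medications$atc_code, cfg$atc_prefixes))
  med_clause <- any(be) && has_med
  ev <- rbind(
    evidence_rows(records, hc, "specific_code_health_condition"),
    if (med_clause) evidence_rows(records, be, "specific_code_with_medication"),
    if (temporal) evidence_rows(records, be, "repeated_billing_encounter")
  )
  result(records, "cd3", any(hc) || med_clause || temporal, ev)
}

#' @rdname cd1
#' @export
cd4 <- function(records, cfg = definition_config()) {
  records <- as_patient_records(records)
  is_spec <- icd_normalize(records$code) == icd_normalize(cfg$specific_code)
  in_range <- icd_in_range(records$code,
    cfg$chapter_range[1], cfg$chapter_range[2])
  mention <- contains_ptsd(records$diagnosis_text, cfg$lexicon)
  text_hit <- if (cfg$patient_level_text) {
    in_range & any(mention)
  } else {
    in_range & mention
  }
  ev <- rbind(
    evidence_rows(records, is_spec, "specific_code_any_source"),
    evidence_rows(records, text_hit, "chapter_code_with_text_mention")
  )
  result(records, "cd4", any(is_spec) || any(text_hit), ev)
}

as_patient_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(tibble::tibble(patient_id = character(), source = character(),
      code = character(), date = as.Date(character()),
      diagnosis_text = character()))
  }
  records <- tibble::as_tibble(records)
  if (!"patient_id" %in% names(records)) records$patient_id <- NA_character_
  if (!"diagnosis_text" %in% names(records)) {
    records$diagnosis_text <- NA_character_
  }
  if (length(unique(records$patient_id)) > 1) {
    stop("records must all belong to one patient", call. = FALSE)
  }
  records$date <- parse_emr_date(records$date)
  records
}

# TRUE iff some pair of dates is >= min_sep days apart; with >= 1 this
# makes duplicate same-day rows count once.
separated_pair <- function(dates, min_sep) {
  dates <- dates[!is.na(dates)]
  length(dates) >= 2 &&
    as.numeric(max(dates) - min(dates)) >= min_sep
}

evidence_rows <- function(records, hit, clause) {
  if (!any(hit)) return(NULL)
  ev <- records[hit, c("patient_id", "source", "code", "date"), drop = FALSE]
  ev$clause <- clause
  ev
}

result <- function(records, definition_id, positive, evidence) {
  pid <- if (nrow(records)) records$patient_id[1] else NA_character_
  if (is.null(evidence)) {
    evidence <- tibble::tibble(patient_id = character(), source = character(),
      code = character(), date = as.Date(character()), clause = character())
  }
  structure(
    list(patient_id = pid, definition_id = definition_id,
         positive = isTRUE(positive),
         evidence = tibble::as_tibble(evidence)),
    class = "case_definition_result"
  )
}

#' @export
print.case_definition_result <- function(x, ...) {
  cat(sprintf("<case_definition_result> %s patient %s: %s (%d evidence row%s)\n",
    toupper(x$definition_id), x$patient_id %||% "?",
    if (x$positive) "positive" else "negative",
    nrow(x$evidence), if (nrow(x$evidence) == 1) "" else "s"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Apply a case definition across a cohort
#'
#' Evaluates one case definition for every patient in the dataset
#' (vectorized; patients with no qualifying rows are negative) and returns a
#' per-patient logical call.  `classify_all()` runs several definitions and
#' returns them as columns of one tibble.
#'
#' @param dataset An [emr_dataset].
#' @param definition One of `"cd1"`, `"cd2"`, `"cd3"`, `"cd4"`.
#' @param cfg A [definition_config].
#' @return `classify_cohort()`: a tibble with columns `patient_id` and
#'   `positive`, one row per patient in the dataset, in patient-table order.
#'   `classify_all()`: a tibble with `patient_id` and one logical column per
#'   definition.
#' @examples
#' cfg <- definition_config()
#' ds <- generate_emr(synthetic_config(n_patients = 200, seed = 1))$dataset
#' summary(classify_cohort(ds, "cd4", cfg)$positive)
#' @export
classify_cohort <- function(dataset, definition, cfg = definition_config()) {
  stopifnot(inherits(dataset, "emr_dataset"))
  definition <- match.arg(definition, definition_ids())
  coded <- dataset$coded
  spec <- icd_normalize(cfg$specific_code)
  is_spec <- icd_normalize(coded$code) == spec
  is_be <- coded$source %in% c("billing", "encounter_diagnosis")

  flags <- switch(definition,
    cd1 = tapply_flag(coded$patient_id, is_spec),
    cd2 = {
      hc <- tapply_flag(coded$patient_id, is_spec & coded$source == "health_condition")
      tmp <- temporal_flag(coded, is_spec & is_be, cfg$min_separation_days)
      merge_flags(hc, tmp)
    },
    cd3 = {
      hc <- tapply_flag(coded$patient_id, is_spec & coded$source == "health_condition")
      be <- tapply_flag(coded$patient_id, is_spec & is_be)
      tmp <- temporal_flag(coded, is_spec & is_be, cfg$min_separation_days)
      med <- tapply_flag(dataset$medications$patient_id,
        atc_prefix_match(dataset$medications$atc_code, cfg$atc_prefixes))
      be_med <- and_flags(be, med)
      merge_flags(merge_flags(hc, be_med), tmp)
    },
    cd4 = {
      any_spec <- tapply_flag(coded$patient_id, is_spec)
      in_range <- icd_in_range(coded$code,
        cfg$chapter_range[1], cfg$chapter_range[2])
      mention <- contains_ptsd(coded$diagnosis_text, cfg$lexicon)
      txt <- if (cfg$patient_level_text) {
        and_flags(tapply_flag(coded$patient_id, in_range),
                  tapply_flag(coded$patient_id, mention))
      } else {
        tapply_flag(coded$patient_id, in_range & mention)
      }
      merge_flags(any_spec, txt)
    }
  )

  ids <- dataset$patients$patient_id
  tibble::tibble(
    patient_id = ids,
    positive = unname(flags[ids]) %in% TRUE
  )
}

#' @rdname classify_cohort
#' @param definitions Character vector of definition ids to run.
#' @export
classify_all <- function(dataset, definitions = definition_ids(),
                         cfg = definition_config()) {
  stopifnot(length(definitions) >= 1)
  definitions <- vapply(definitions, match.arg, "", choices = definition_ids())
  out <- tibble::tibble(patient_id = dataset$patients$patient_id)
  for (d in definitions) {
    out[[d]] <- classify_cohort(dataset, d, cfg)$positive
  }
  out
}

# named logical vector: patient id -> any(hit)
tapply_flag <- function(ids, hit) {
  if (!length(ids)) return(stats::setNames(logical(0), character(0)))
  res <- tapply(hit, ids, any)
  stats::setNames(as.logical(res), names(res))
}

# patient id -> some pair of hit-row dates separated by >= min_sep days
temporal_flag <- function(coded, hit, min_sep) {
  ids <- coded$patient_id[hit]
  if (!length(ids)) return(stats::setNames(logical(0), character(0)))
  dates <- as.numeric(coded$date[hit])
  rng <- tapply(dates, ids, function(d) {
    d <- d[!is.na(d)]
    length(d) >= 2 && (max(d) - min(d)) >= min_sep
  })
  stats::setNames(as.logical(rng), names(rng))
}

merge_flags <- function(a, b) {  # union (OR, missing = FALSE)
  ids <- union(names(a), names(b))
  stats::setNames((a[ids] %in% TRUE) | (b[ids] %in% TRUE), ids)
}

and_flags <- function(a, b) {    # intersection (AND, missing = FALSE)
  ids <- union(names(a), names(b))
  stats::setNames((a[ids] %in% TRUE) & (b[ids] %in% TRUE), ids)
}
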