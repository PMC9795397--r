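# Shared fixture builders and an independent brute-force oracle for the
# case-definition clauses.

make_coded <- function(patient_id, source, code, date, text = NA_character_) {
  tibble::tibble(patient_id = patient_id, source = source, code = code,
    date = as.Date(date), diagnosis_text = text)
}

make_meds <- function(patient_id, atc, date = "2019-01-01") {
  tibble::tibble(patient_id = patient_id, atc_code = atc,
    date = as.Date(date))
}

toy_patients <- function(ids, last = "2019-06-01") {
  tibble::tibble(patient_id = ids, birth_year = 1980L, sex = "F",
    region = "MB", last_encounter_date = as.Date(last))
}

# Random single-patient record sets exercising every clause boundary:
# dotted/undotted specific codes, the 3-digit stem, in/out-of-chapter codes,
# V codes, close and distant dates, text with and without PTSD mentions.
random_patient_records <- function(id, max_records = 8) {
  n <- sample(0:max_records, 1)
  if (n == 0) {
    return(make_coded(character(), character(), character(), as.Date(character())))
  }
  make_coded(
    patient_id = rep(id, n),
    source = sample(c("health_condition", "billing", "encounter_diagnosis"),
      n, replace = TRUE),
    code = sample(c("309.81", "30981", "309", "300", "308", "311",
      "250.00", "V70.0", "309.8", "316"), n, replace = TRUE),
    date = as.Date("2019-01-01") + sample(0:20, n, replace = TRUE),
    text = sample(c(NA, "", "PTSD", "ptsd f/u", "anxiety", "p.t.s.d.",
      "post traumatic stress disorder", "depression", "no concerns"),
      n, replace = TRUE)
  )
}

random_patient_meds <- function(id) {
  n <- sample(0:2, 1)
  make_meds(rep(id, n),
    atc = sample(c("N05BA01", "N06AB06", "C09AA05", "A02BC01"), n,
      replace = TRUE))
}

# Brute-force clause enumeration, written independently of the engine:
# plain loops, literal clause-by-clause evaluation.
oracle_norm <- function(code) toupper(gsub("[. ]", "", code))

oracle_definition <- function(definition, records, meds, cfg) {
  spec <- oracle_norm(cfg$specific_code)
  n <- nrow(records)
  is_spec <- rep(FALSE, n)
  for (i in seq_len(n)) is_spec[i] <- oracle_norm(records$code[i]) == spec

  any_spec <- any(is_spec)
  hc_spec <- FALSE
  for (i in seq_len(n)) {
    if (is_spec[i] && records$source[i] == "health_condition") hc_spec <- TRUE
  }
  be_idx <- integer(0)
  for (i in seq_len(n)) {
    if (is_spec[i] &&
        records$source[i] %in% c("billing", "encounter_diagnosis")) {
      be_idx <- c(be_idx, i)
    }
  }
  pair_sep <- FALSE
  for (i in be_idx) {
    for (j in be_idx) {
      if (i < j && abs(as.numeric(records$date[i] - records$date[j])) >=
            cfg$min_separation_days) {
        pair_sep <- TRUE
      }
    }
  }
  any_med <- FALSE
  for (i in seq_len(nrow(meds))) {
    atc <- toupper(meds$atc_code[i])
    for (p in cfg$atc_prefixes) {
      if (substr(atc, 1, nchar(p)) == toupper(p)) any_med <- TRUE
    }
  }
  text_clause <- FALSE
  for (i in seq_len(n)) {
    norm <- oracle_norm(records$code[i])
    stem <- suppressWarnings(as.integer(substr(norm, 1, 3)))
    in_range <- !is.na(stem) && grepl("^[0-9]{3}", norm) &&
      stem >= cfg$chapter_range[1] && stem <= cfg$chapter_range[2]
    if (in_range && isTRUE(contains_ptsd(records$diagnosis_text[i],
        cfg$lexicon))) {
      text_clause <- TRUE
    }
  }

  switch(definition,
    cd1 = any_spec,
    cd2 = hc_spec || pair_sep,
    cd3 = hc_spec || (length(be_idx) > 0 && any_med) || pair_sep,
    cd4 = any_spec || text_clause
  )
}
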