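#' Configuration for the synthetic EMR generator
#'
#' Parameters of the generative model used to emulate a multi-table primary
#' care EMR extract with the coding and text pathways the case definitions
#' rely on.  Each true PTSD case may independently acquire: a health
#' condition row with the specific code 309.81; up to `k_billing`
#' billing rows with the specific code (truncated to the 3-digit stem
#' "309" for patients in jurisdictions whose billing rules only allow
#' 3-digit codes); and one to three related mental-health rows (ICD-9-CM
#' 300, 308, 309, 311) in the encounter diagnosis table.  Every
#' mental-health-coded row of a true case carries a PTSD mention in its
#' short diagnostic text with probability `p_text_mention`, written as the
#' canonical "PTSD" or, with probability `misspelling_rate`, as a
#' non-canonical lexicon variant.  Non-cases receive related
#' mental-health codes at rate `p_related_codes_neg` (never with a PTSD
#' mention) and both groups receive psychotropic (ATC N05/N06) and
#' unrelated medications and diagnoses at background rates.
#'
#' The defaults put the closed-form expected CD1 sensitivity
#' (see [expected_cd1_sensitivity()]) near 72% and the text-supplemented
#' CD4 near 91%, illustrating a jurisdiction mix in which roughly a
#' quarter of billing is truncated; they are illustrative, not fitted.
#'
#' @param n_patients Number of patients to simulate.
#' @param prevalence Proportion of patients who truly have PTSD.
#' @param p_hc_specific Probability a case gets a health condition 309.81 row.
#' @param p_billing_specific Per-slot probability of each of `k_billing`
#'   billing 309.81 rows for a case.
#' @param k_billing Number of independent billing-row slots per case.
#' @param p_truncated_region Proportion of patients in a jurisdiction whose
#'   billing codes are truncated to 3 digits.
#' @param p_text_mention Probability a mental-health-coded row of a case
#'   carries a PTSD text mention.
#' @param misspelling_rate Probability a mention uses a non-canonical
#'   variant rather than "PTSD".
#' @param p_related_codes_neg Probability a non-case receives a related
#'   mental-health code row.
#' @param p_med_case,p_med_control Probability of an ATC N05/N06 medication
#'   row for cases and non-cases.
#' @param reviewer_error Per-reviewer probability of mislabeling a patient
#'   during simulated chart review.
#' @param p_adjudicate Probability a reviewer disagreement is adjudicated
#'   (to the true status); otherwise the patient is labeled
#'   `possible_PTSD` and excluded downstream.
#' @param date_range Two ISO dates bounding all record dates (uniform).
#' @param seed Mandatory RNG seed (integer below 2^31 - 2); the generator is
#'   fully reproducible given the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 10000,
                             prevalence = 0.014,
                             p_hc_specific = 0.42,
                             p_billing_specific = 0.45,
                             k_billing = 2,
                             p_truncated_region = 0.25,
                             p_text_mention = 0.45,
                             misspelling_rate = 0.3,
                             p_related_codes_neg = 0.3,
                             p_med_case = 0.6,
                             p_med_control = 0.1,
                             reviewer_error = 0.05,
                             p_adjudicate = 0.9,
                             date_range = c("2017-01-01", "2019-12-31"),
                             seed) {
  if (missing(seed)) stop("synthetic_config requires a seed", call. = FALSE)
  probs <- c(prevalence = prevalence, p_hc_specific = p_hc_specific,
    p_billing_specific = p_billing_specific,
    p_truncated_region = p_truncated_region,
    p_text_mention = p_text_mention, misspelling_rate = misspelling_rate,
    p_related_codes_neg = p_related_codes_neg, p_med_case = p_med_case,
    p_med_control = p_med_control, reviewer_error = reviewer_error,
    p_adjudicate = p_adjudicate)
  bad <- names(probs)[probs < 0 | probs > 1 | is.na(probs)]
  if (length(bad)) {
    stop("config error: probabilities outside [0, 1]: ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_patients >= 1, k_billing >= 0, length(date_range) == 2)
  date_range <- parse_emr_date(date_range)
  stopifnot(date_range[1] <= date_range[2])
  structure(
    c(as.list(probs),
      list(n_patients = as.integer(n_patients),
           k_billing = as.integer(k_billing),
           date_range = date_range, seed = as.integer(seed))),
    class = "synthetic_config"
  )
}

mental_health_stems <- function() c("300", "308", "309", "311")
psychotropic_atc <- function() {
  c("N05BA01", "N05AH04", "N05CF01", "N06AB06", "N06AA09", "N06AX16")
}
other_atc <- function() c("C09AA05", "A02BC01", "M01AE01", "R03AC02")
background_text <- function() {
  c("anxiety", "anxiety NOS", "depression", "low mood", "stress reaction",
    "adjustment reaction", "insomnia", "counselling", "follow-up")
}
mention_variants <- function() {
  c("p.t.s.d.", "ptss", "ptds", "post traumatic stress disorder",
    "post-traumatic stress", "posttraumatic stress disorder")
}

#' Generate a synthetic EMR dataset with known case status
#'
#' Simulates the five-table extract under the pathway model described in
#' [synthetic_config()], returning the dataset together with the truth
#' table (the latent case status that drives generation and is never
#' written into the EMR tables themselves).
#'
#' @param cfg A [synthetic_config].
#' @return A list with `dataset` (an [emr_dataset], labels unset) and
#'   `truth` (tibble `patient_id`, `ptsd`).
#' @examples
#' sim <- generate_emr(synthetic_config(n_patients = 500, seed = 42))
#' sim$dataset
#' mean(sim$truth$ptsd)
#' @export
generate_emr <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, generate_emr_impl(cfg))
}

generate_emr_impl <- function(cfg) {
  n <- cfg$n_patients
  ids <- sprintf("pt%06d", seq_len(n))
  ptsd <- runif(n) < cfg$prevalence
  truncated <- runif(n) < cfg$p_truncated_region
  region <- ifelse(truncated, "ON",
    sample(c("MB", "AB", "BC", "QC", "NS", "NL"), n, replace = TRUE))
  patients <- tibble::tibble(
    patient_id = ids,
    birth_year = sample(1930:2005, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45)),
    region = region,
    last_encounter_date = random_date(n, cfg$date_range)
  )

  case_ids <- ids[ptsd]
  case_trunc <- truncated[ptsd]
  rows <- list()

  # Case pathway: health condition row with the specific code.
  has_hc <- runif(length(case_ids)) < cfg$p_hc_specific
  rows$hc <- coded_rows(case_ids[has_hc], "health_condition", "309.81", cfg,
    mention_eligible = TRUE)

  # Case pathway: up to k_billing billing rows; 3-digit stem where truncated.
  for (j in seq_len(cfg$k_billing)) {
    has_b <- runif(length(case_ids)) < cfg$p_billing_specific
    code <- ifelse(case_trunc[has_b], "309", "309.81")
    rows[[paste0("billing", j)]] <- coded_rows(case_ids[has_b], "billing",
      code, cfg, mention_eligible = TRUE)
  }

  # Case pathway: 1-3 related mental-health encounter diagnoses.
  n_rel <- 1 + rbinom(length(case_ids), 2, 0.5)
  rel_ids <- rep(case_ids, n_rel)
  rows$related_case <- coded_rows(rel_ids, "encounter_diagnosis",
    sample(mental_health_stems(), length(rel_ids), replace = TRUE),
    cfg, mention_eligible = TRUE)

  # Background pathway: non-cases with related mental-health codes.
  ctrl_ids <- ids[!ptsd]
  has_rel <- runif(length(ctrl_ids)) < cfg$p_related_codes_neg
  bg_ids <- ctrl_ids[has_rel]
  rows$related_ctrl <- coded_rows(bg_ids,
    sample(c("billing", "encounter_diagnosis"), length(bg_ids), replace = TRUE),
    sample(mental_health_stems(), length(bg_ids), replace = TRUE),
    cfg, mention_eligible = FALSE)

  # Background pathway: unrelated chronic-disease codes for everyone.
  has_other <- runif(n) < 0.4
  oth_ids <- ids[has_other]
  rows$other <- coded_rows(oth_ids,
    sample(coded_sources(), length(oth_ids), replace = TRUE),
    sample(c("250.00", "401.1", "715.9", "493.90"), length(oth_ids),
      replace = TRUE),
    cfg, mention_eligible = FALSE)

  coded <- dplyr::bind_rows(rows)

  # Medications: psychotropics at case/control rates plus unrelated drugs.
  med_p <- ifelse(ptsd, cfg$p_med_case, cfg$p_med_control)
  has_psy <- runif(n) < med_p
  has_oth <- runif(n) < 0.3
  medications <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids[has_psy],
      atc_code = sample(psychotropic_atc(), sum(has_psy), replace = TRUE),
      date = random_date(sum(has_psy), cfg$date_range)),
    tibble::tibble(patient_id = ids[has_oth],
      atc_code = sample(other_atc(), sum(has_oth), replace = TRUE),
      date = random_date(sum(has_oth), cfg$date_range))
  )

  # Last encounter follows the latest recorded activity where there is any.
  activity <- c(stats::setNames(as.numeric(coded$date), coded$patient_id),
    stats::setNames(as.numeric(medications$date), medications$patient_id))
  if (length(activity)) {
    latest <- tapply(activity, names(activity), max)
    hit <- match(patients$patient_id, names(latest))
    patients$last_encounter_date[!is.na(hit)] <-
      as.Date(unname(latest[hit[!is.na(hit)]]), origin = "1970-01-01")
  }

  dataset <- emr_dataset(patients, coded, medications)
  list(dataset = dataset,
       truth = tibble::tibble(patient_id = ids, ptsd = ptsd))
}

# Build coded rows for a set of patients; mental-health rows of true cases
# are eligible for a PTSD text mention.
coded_rows <- function(patient_id, source, code, cfg, mention_eligible) {
  m <- length(patient_id)
  if (m == 0) {
    return(tibble::tibble(patient_id = character(), source = character(),
      code = character(), date = as.Date(character()),
      diagnosis_text = character()))
  }
  text <- sample(background_text(), m, replace = TRUE)
  if (mention_eligible) {
    mention <- runif(m) < cfg$p_text_mention
    misspelled <- runif(m) < cfg$misspelling_rate
    text[mention] <- ifelse(misspelled[mention],
      sample(mention_variants(), sum(mention), replace = TRUE), "PTSD")
  }
  tibble::tibble(
    patient_id = patient_id,
    source = rep_len(source, m),
    code = rep_len(code, m),
    date = random_date(m, cfg$date_range),
    diagnosis_text = text
  )
}

random_date <- function(m, range) {
  span <- as.integer(range[2] - range[1])
  range[1] + floor(runif(m) * (span + 1))
}

#' Simulate dual-reviewer chart review with adjudication
#'
#' Emulates the reference-labeling process of a validation study: two
#' independent reviewers each label every patient, flipping the true status
#' with probability `reviewer_error`.  When they agree, their common call
#' becomes the final label; when they disagree, the case is adjudicated to
#' the true status with probability `p_adjudicate` and otherwise labeled
#' `possible_PTSD`, which downstream agreement statistics exclude.
#'
#' @param truth Tibble with columns `patient_id` and `ptsd`, as returned by
#'   [generate_emr()].
#' @param cfg The [synthetic_config] (supplies `reviewer_error`,
#'   `p_adjudicate`, and the seed; the review uses its own RNG stream
#'   derived from `seed + 1`).
#' @return Tibble with columns `patient_id`, `label`, `source`
#'   (`"simulated"`), suitable as the `labels` table of an [emr_dataset].
#' @examples
#' cfg <- synthetic_config(n_patients = 200, seed = 7)
#' sim <- generate_emr(cfg)
#' table(simulate_review(sim$truth, cfg)$label)
#' @export
simulate_review <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"),
    all(c("patient_id", "ptsd") %in% names(truth)))
  withr::with_seed(cfg$seed + 1L, {
    n <- nrow(truth)
    r1 <- xor(truth$ptsd, runif(n) < cfg$reviewer_error)
    r2 <- xor(truth$ptsd, runif(n) < cfg$reviewer_error)
    adjudicated <- runif(n) < cfg$p_adjudicate
    label <- ifelse(r1 == r2,
      ifelse(r1, "PTSD", "no_PTSD"),
      ifelse(adjudicated, ifelse(truth$ptsd, "PTSD", "no_PTSD"),
        "possible_PTSD"))
    tibble::tibble(patient_id = truth$patient_id, label = label,
      source = "simulated")
  })
}

#' Closed-form expected CD1 sensitivity under the generative model
#'
#' Under the pathway model, a true case is CD1-detectable iff it acquires a
#' health condition 309.81 row or at least one untruncated billing 309.81
#' row; the pathways are independent, so
#' `1 - (1 - p_hc_specific) * (1 - p_billing_effective)` with
#' `p_billing_effective = (1 - p_truncated_region) *
#' (1 - (1 - p_billing_specific)^k_billing)`.  Used as the target in
#' parameter-recovery checks of the generator.
#'
#' @param cfg A [synthetic_config].
#' @return Expected CD1 sensitivity as a probability.
#' @examples
#' expected_cd1_sensitivity(synthetic_config(seed = 1))
#' @export
expected_cd1_sensitivity <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p_billing_effective <- (1 - cfg$p_truncated_region) *
    (1 - (1 - cfg$p_billing_specific)^cfg$k_billing)
  1 - (1 - cfg$p_hc_specific) * (1 - p_billing_effective)
}
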