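cfg <- definition_config()

test_that("cd1 requires the specific code in any of the three sources", {
  expect_true(cd1(make_coded("p", "billing", "309.81", "2019-01-01"), cfg)$positive)
  expect_true(cd1(make_coded("p", "billing", "30981", "2019-01-01"), cfg)$positive)
  expect_false(cd1(make_coded("p", "billing", "309", "2019-01-01"), cfg)$positive)
  expect_false(cd1(make_coded(c("p", "p"), c("health_condition", "billing"),
    c("300.0", "311"), c("2019-01-01", "2019-01-02")), cfg)$positive)
  empty <- make_coded(character(), character(), character(), as.Date(character()))
  expect_false(cd1(empty, cfg)$positive)
})

test_that("cd2 needs a health-condition code or two separated billing rows", {
  expect_true(cd2(make_coded("p", "health_condition", "309.81", "2019-01-01"),
    cfg)$positive)
  two <- function(gap) make_coded(c("p", "p"), "billing", "309.81",
    as.Date("2019-01-01") + c(0, gap))
  expect_true(cd2(two(10), cfg)$positive)
  expect_true(cd2(two(7), cfg)$positive)   # inclusive at exactly one week
  expect_false(cd2(two(3), cfg)$positive)
  expect_false(cd2(two(0), cfg)$positive)  # same-day duplicates count once
  expect_false(cd2(make_coded("p", "billing", "309.81", "2019-01-01"),
    cfg)$positive)
  # min_separation_days = 0 degenerates to a pure count rule
  cfg0 <- definition_config(min_separation_days = 0)
  expect_true(cd2(two(0), cfg0)$positive)
})

test_that("cd3 adds the medication clause", {
  one_billing <- make_coded("p", "billing", "309.81", "2019-01-01")
  expect_true(cd3(one_billing, make_meds("p", "N05BA01"), cfg)$positive)
  expect_true(cd3(one_billing, make_meds("p", "N06AB06"), cfg)$positive)
  expect_false(cd3(one_billing, make_meds("p", "C09AA05"), cfg)$positive)
  expect_false(cd3(one_billing, NULL, cfg)$positive)
  expect_true(cd3(make_coded("p", "health_condition", "309.81", "2019-01-01"),
    NULL, cfg)$positive)
  # medication alone is never sufficient
  empty <- make_coded(character(), character(), character(), as.Date(character()))
  expect_false(cd3(empty, make_meds("p", "N05BA01"), cfg)$positive)
})

test_that("cd4 adds chapter codes whose own text names PTSD", {
  row309 <- make_coded("p", "billing", "309", "2019-01-01", "ptsd")
  expect_true(cd4(row309, cfg)$positive)
  expect_false(cd1(row309, cfg)$positive)
  expect_false(cd4(make_coded("p", "billing", "250.00", "2019-01-01", "ptsd"),
    cfg)$positive)
  expect_true(cd4(make_coded("p", "health_condition", "309.81", "2019-01-01", ""),
    cfg)$positive)
  # row-level pairing by default: mention must sit on the in-chapter row
  split <- make_coded(c("p", "p"), "billing", c("309", "250.00"),
    c("2019-01-01", "2019-01-02"), c("anxiety", "ptsd"))
  expect_false(cd4(split, cfg)$positive)
  cfg_pl <- definition_config(patient_level_text = TRUE)
  expect_true(cd4(split, cfg_pl)$positive)
})

test_that("results carry the evidence rows that fired", {
  res <- cd2(make_coded(c("p", "p", "p"),
    c("health_condition", "billing", "billing"),
    c("309.81", "309.81", "300"),
    c("2019-01-01", "2019-03-01", "2019-03-02")), cfg)
  expect_true(res$positive)
  expect_true("specific_code_health_condition" %in% res$evidence$clause)
  expect_false("300" %in% res$evidence$code)
  neg <- cd1(make_coded("p", "billing", "300", "2019-01-01"), cfg)
  expect_equal(nrow(neg$evidence), 0)
})

test_that("classify_cohort matches per-patient evaluation and is deterministic", {
  coded <- dplyr::bind_rows(
    make_coded("a", "billing", "309.81", "2019-01-01"),          # CD1+
    make_coded("b", "billing", "309", "2019-01-02", "PTSD"),     # CD4-only
    make_coded("c", "billing", "311", "2019-01-03", "anxiety")   # negative
  )
  ds <- emr_dataset(toy_patients(c("a", "b", "c", "d")), coded)
  out <- classify_cohort(ds, "cd4", cfg)
  expect_equal(out$positive, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out, classify_cohort(ds, "cd4", cfg))
  expect_equal(classify_cohort(ds, "cd1", cfg)$positive,
    c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_cohort(ds, "cd9", cfg))
  all4 <- classify_all(ds, cfg = cfg)
  expect_equal(all4$cd4, out$positive)
})

test_that("engine equals the brute-force clause oracle on random patients", {
  withr::local_seed(2024)
  cfgs <- list(cfg, definition_config(min_separation_days = 10),
    definition_config(patient_level_text = TRUE))
  for (cc in cfgs) {
    for (rep in 1:120) {
      id <- paste0("p", rep)
      recs <- random_patient_records(id)
      meds <- random_patient_meds(id)
      expect_equal(cd1(recs, cc)$positive, oracle_definition("cd1", recs, meds, cc))
      expect_equal(cd2(recs, cc)$positive, oracle_definition("cd2", recs, meds, cc))
      expect_equal(cd3(recs, meds, cc)$positive,
        oracle_definition("cd3", recs, meds, cc))
      if (!cc$patient_level_text) {
        expect_equal(cd4(recs, cc)$positive,
          oracle_definition("cd4", recs, meds, cc))
      }
    }
  }
})

test_that("cohort and per-patient paths agree on a generated dataset", {
  sim <- generate_emr(synthetic_config(n_patients = 400, prevalence = 0.2,
    seed = 5))
  ds <- sim$dataset
  for (d in c("cd1", "cd2", "cd3", "cd4")) {
    cohort <- classify_cohort(ds, d, cfg)
    per_patient <- vapply(cohort$patient_id, function(id) {
      recs <- ds$coded[ds$coded$patient_id == id, ]
      meds <- ds$medications[ds$medications$patient_id == id, ]
      switch(d,
        cd1 = cd1(recs, cfg)$positive,
        cd2 = cd2(recs, cfg)$positive,
        cd3 = cd3(recs, meds, cfg)$positive,
        cd4 = cd4(recs, cfg)$positive)
    }, logical(1))
    expect_equal(cohort$positive, unname(per_patient), info = d)
  }
})

test_that("definitions nest: CD2 within CD3 within CD1 within CD4", {
  sim <- generate_emr(synthetic_config(n_patients = 2000, prevalence = 0.1,
    seed = 77))
  calls <- classify_all(sim$dataset, cfg = cfg)
  expect_true(all(!calls$cd2 | calls$cd3))
  expect_true(all(!calls$cd3 | calls$cd1))
  expect_true(all(!calls$cd1 | calls$cd4))
})

test_that("cd4 with an empty lexicon degenerates to cd1", {
  sim <- generate_emr(synthetic_config(n_patients = 1500, prevalence = 0.1,
    seed = 99))
  cfg_empty <- definition_config(lexicon = ptsd_lexicon(variants = character(0)))
  expect_equal(classify_cohort(sim$dataset, "cd4", cfg_empty)$positive,
               classify_cohort(sim$dataset, "cd1", cfg_empty)$positive)
})
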