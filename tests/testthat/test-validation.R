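test_that("confusion_matrix counts cells and excludes possible_PTSD", {
  ids <- paste0("p", 1:10)
  ref <- tibble::tibble(patient_id = ids,
    label = rep(c("PTSD", "no_PTSD"), c(6, 4)))
  perfect <- tibble::tibble(patient_id = ids,
    positive = rep(c(TRUE, FALSE), c(6, 4)))
  cm <- confusion_matrix(perfect, ref)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
    list(tp = 6L, tn = 4L, fp = 0L, fn = 0L))

  all_neg <- tibble::tibble(patient_id = ids, positive = FALSE)
  cm2 <- confusion_matrix(all_neg, ref)
  expect_equal(c(cm2$tp, cm2$tn, cm2$fp, cm2$fn), c(0, 4, 0, 6))

  ref$label[1] <- "possible_PTSD"
  cm3 <- confusion_matrix(perfect, ref)
  expect_equal(cm3$tp + cm3$tn + cm3$fp + cm3$fn, 9)

  expect_error(confusion_matrix(perfect[-2, ], ref), "missing a prediction.*p2")
})

test_that("confusion_matrix matches a count-by-hand tally on random fixtures", {
  withr::local_seed(42)
  for (rep in 1:5) {
    ids <- paste0("p", 1:20)
    truth <- sample(c("PTSD", "no_PTSD", "possible_PTSD"), 20, replace = TRUE,
      prob = c(0.4, 0.5, 0.1))
    pred <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    cm <- confusion_matrix(tibble::tibble(patient_id = ids, positive = pred),
      tibble::tibble(patient_id = ids, label = truth))
    tp <- tn <- fp <- fn <- 0
    for (i in 1:20) {
      if (truth[i] == "possible_PTSD") next
      if (pred[i] && truth[i] == "PTSD") tp <- tp + 1
      if (pred[i] && truth[i] == "no_PTSD") fp <- fp + 1
      if (!pred[i] && truth[i] == "PTSD") fn <- fn + 1
      if (!pred[i] && truth[i] == "no_PTSD") tn <- tn + 1
    }
    expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(tp, tn, fp, fn))
  }
})

test_that("agreement metrics handle degenerate tables without fake zeros", {
  all100 <- agreement_metrics(new_confusion_matrix(1, 1, 0, 0))
  expect_equal(all100$estimate, rep(100, 5))
  expect_true(all(all100$lower <= all100$estimate &
                  all100$estimate <= all100$upper))

  no_pos <- agreement_metrics(new_confusion_matrix(0, 5, 0, 0))
  expect_true(is.na(no_pos$estimate[no_pos$metric == "sensitivity"]))
  expect_true(is.na(no_pos$estimate[no_pos$metric == "ppv"]))
  expect_equal(no_pos$estimate[no_pos$metric == "accuracy"], 100)
})

test_that("clopper_pearson boundaries, closed form, and binom.test agreement", {
  expect_equal(clopper_pearson(50, 50)[["upper"]], 1)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(0, 10)[["upper"]], 1 - 0.025^(1 / 10))
  expect_equal(round_half_up(100 * clopper_pearson(0, 10)[["upper"]], 2), 30.85)

  # independent route: stats::binom.test implements the same exact interval
  withr::local_seed(7)
  for (i in 1:25) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson(k, n)),
      as.numeric(binom.test(k, n)$conf.int), tolerance = 1e-12)
  }
  expect_equal(unname(round_half_up(100 * clopper_pearson(214, 215), 1)),
    c(97.4, 100))
})

test_that("wilson interval is a sane alternative", {
  ci <- wilson_interval(8, 10)
  expect_true(ci[["lower"]] < 0.8 && 0.8 < ci[["upper"]])
  expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
  m <- agreement_metrics(new_confusion_matrix(8, 5, 2, 2), ci_method = "wilson")
  expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
})

test_that("CI width shrinks with n at fixed proportion; estimate inside CI", {
  widths <- vapply(c(10, 100, 1000, 10000), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  m <- agreement_metrics(new_confusion_matrix(30, 50, 10, 10))
  expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
  expect_true(all(m$estimate >= 0 & m$estimate <= 100))
})

test_that("swapping the positive label swaps sens/spec and ppv/npv", {
  cm <- new_confusion_matrix(tp = 30, tn = 55, fp = 7, fn = 12)
  swapped <- new_confusion_matrix(tp = 55, tn = 30, fp = 12, fn = 7)
  a <- agreement_metrics(cm)
  b <- agreement_metrics(swapped)
  get <- function(m, what) m$estimate[m$metric == what]
  expect_equal(get(a, "sensitivity"), get(b, "specificity"))
  expect_equal(get(a, "specificity"), get(b, "sensitivity"))
  expect_equal(get(a, "ppv"), get(b, "npv"))
  expect_equal(get(a, "npv"), get(b, "ppv"))
  expect_equal(get(a, "accuracy"), get(b, "accuracy"))
})

test_that("prevalence is exact before rounding and validates inputs", {
  p <- prevalence(7718, 689301)
  expect_equal(p$proportion * p$n_population / 100, 7718)
  expect_true(p$lower <= p$proportion && p$proportion <= p$upper)
  z <- prevalence(0, 1000)
  expect_equal(z$proportion, 0)
  expect_equal(z$lower, 0)
  expect_error(prevalence(11, 10), "exceeds")
})

test_that("small-cell suppression masks with complementary protection", {
  view <- suppress_small_cells(new_confusion_matrix(tp = 95, tn = 214,
    fp = 1, fn = 20), threshold = 5)
  expect_equal(view[["fp"]], "<5")
  expect_equal(view[["fn"]], "suppressed")
  expect_equal(view[["tp"]], "95")

  none <- suppress_small_cells(new_confusion_matrix(95, 214, 1, 20),
    threshold = 0)
  expect_equal(unname(none), c("95", "214", "20", "1"))
  big <- suppress_small_cells(new_confusion_matrix(50, 60, 70, 80),
    threshold = 5)
  expect_equal(unname(big), c("50", "60", "80", "70"))
  # two cells already below threshold: no extra complementary mask needed
  two <- suppress_small_cells(new_confusion_matrix(95, 214, 1, 2))
  expect_equal(sum(two %in% c("<5")), 2)
  expect_false("suppressed" %in% two)
})

test_that("reporting rounds half away from zero, two-stage for published style", {
  expect_equal(round_half_up(c(1.25, 1.35, -1.25), 1), c(1.3, 1.4, -1.3))
  expect_equal(round_half_up(82.55, 1), 82.6)
  expect_equal(round_published(100 * 3672 / 4033), 91.1)
  expect_equal(round_half_up(100 * 3672 / 4033, 1), 91.0)
})
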