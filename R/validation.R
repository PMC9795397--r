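#' Confusion matrix against a chart-review reference standard
#'
#' Cross-tabulates predicted case status against reference labels.  Patients
#' labeled `possible_PTSD` are removed before counting — they are excluded
#' from any reference standard used for agreement metrics — and every
#' remaining reference patient must have a prediction.
#'
#' @param predicted A tibble with columns `patient_id` and `positive`
#'   (as returned by [classify_cohort()]), or a named logical vector.
#' @param reference A tibble with columns `patient_id` and `label`
#'   (`"PTSD"`, `"no_PTSD"`, `"possible_PTSD"`), e.g. the `labels` table of
#'   an [emr_dataset] restricted to one source.
#' @return An object of class `confusion_matrix`: a list with integer
#'   counts `tp`, `tn`, `fp`, `fn`.
#' @examples
#' cm <- confusion_matrix(
#'   data.frame(patient_id = c("a", "b", "c"), positive = c(TRUE, FALSE, TRUE)),
#'   data.frame(patient_id = c("a", "b", "c"),
#'              label = c("PTSD", "no_PTSD", "no_PTSD"))
#' )
#' agreement_metrics(cm)
#' @export
confusion_matrix <- function(predicted, reference) {
  if (is.logical(predicted) && !is.null(names(predicted))) {
    predicted <- tibble::tibble(patient_id = names(predicted),
      positive = unname(predicted))
  }
  stopifnot(is.data.frame(predicted),
    all(c("patient_id", "positive") %in% names(predicted)),
    is.data.frame(reference),
    all(c("patient_id", "label") %in% names(reference)))
  bad <- setdiff(unique(reference$label), label_levels())
  if (length(bad)) {
    stop("unknown reference label(s): ", paste(bad, collapse = ", "),
      call. = FALSE)
  }
  ref <- reference[reference$label != "possible_PTSD", ]
  if (anyDuplicated(ref$patient_id)) {
    stop("reference contains more than one label for some patient(s)",
      call. = FALSE)
  }
  pred <- stats::setNames(predicted$positive, predicted$patient_id)
  missing <- setdiff(ref$patient_id, names(pred))
  if (length(missing)) {
    stop("reference patient(s) missing a prediction: ",
      paste(head(missing, 10), collapse = ", "), call. = FALSE)
  }
  p <- pred[ref$patient_id] %in% TRUE
  truth <- ref$label == "PTSD"
  new_confusion_matrix(
    tp = sum(p & truth), tn = sum(!p & !truth),
    fp = sum(p & !truth), fn = sum(!p & truth)
  )
}

#' @rdname confusion_matrix
#' @param tp,tn,fp,fn Non-negative cell counts, for building a confusion
#'   matrix directly from published tables.
#' @export
new_confusion_matrix <- function(tp, tn, fp, fn) {
  cells <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(!is.na(cells)), all(cells >= 0),
    all(cells == as.integer(cells)))
  cells <- as.integer(cells)
  structure(list(tp = cells[1], tn = cells[2], fp = cells[3], fn = cells[4]),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>  n =", x$tp + x$tn + x$fp + x$fn, "\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
    dimnames = list(predicted = c("positive", "negative"),
                    reference = c("PTSD", "no_PTSD")))
  print(m)
  invisible(x)
}

#' Agreement metrics with exact binomial confidence intervals
#'
#' Computes the five agreement statistics of a diagnostic validation study
#' from a 2x2 contingency table: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive predictive value `tp/(tp+fp)`, negative predictive
#' value `tn/(tn+fn)`, and overall accuracy `(tp+tn)/n`, each expressed as a
#' percentage with a two-sided confidence interval.  A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param cm A [confusion_matrix].
#' @param alpha Two-sided significance level; 0.05 gives 95% intervals.
#' @param ci_method `"clopper-pearson"` (exact binomial, the default) or
#'   `"wilson"` (score interval).
#' @return A tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `lower`, `upper` (percentages, full
#'   precision; round only for reporting, e.g. with [round_half_up()]).
#' @examples
#' agreement_metrics(new_confusion_matrix(tp = 3672, tn = 8000,
#'                                        fp = 71, fn = 361))
#' @export
agreement_metrics <- function(cm, alpha = 0.05,
                              ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  spec <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn),
    accuracy = c(cm$tp + cm$tn, n)
  )
  rows <- lapply(names(spec), function(m) {
    k <- spec[[m]][1]; d <- spec[[m]][2]
    if (d == 0) {
      tibble::tibble(metric = m, numerator = k, denominator = d,
        estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- binomial_interval(k, d, alpha, ci_method)
      tibble::tibble(metric = m, numerator = k, denominator = d,
        estimate = 100 * k / d, lower = 100 * ci[1], upper = 100 * ci[2])
    }
  })
  dplyr::bind_rows(rows)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for a binomial proportion, from beta-distribution
#' quantiles: the lower bound is the `alpha/2` quantile of `Beta(k, n-k+1)`
#' (0 when `k = 0`) and the upper bound the `1-alpha/2` quantile of
#' `Beta(k+1, n-k)` (1 when `k = n`).  At `k = 0` the upper bound has the
#' closed form `1 - (alpha/2)^(1/n)`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param alpha Two-sided significance level.
#' @return Numeric vector `c(lower, upper)` on the proportion (0-1) scale.
#' @examples
#' clopper_pearson(214, 215)      # c(0.974..., 1)
#' clopper_pearson(0, 10)         # upper = 1 - 0.025^(1/10)
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n,
    alpha > 0, alpha < 1)
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' @rdname clopper_pearson
#' @export
wilson_interval <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - alpha / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

binomial_interval <- function(k, n, alpha, method) {
  switch(method,
    "clopper-pearson" = clopper_pearson(k, n, alpha),
    "wilson" = wilson_interval(k, n, alpha))
}

#' Prevalence with an exact binomial confidence interval
#'
#' Point prevalence of a case definition in a population, as a percentage,
#' with the exact binomial (Clopper-Pearson) interval.
#'
#' @param n_cases Number of patients the definition captures.
#' @param n_population Size of the population (e.g. active patients).
#' @param alpha Two-sided significance level.
#' @return A tibble with `n_cases`, `n_population`, `proportion`, `lower`,
#'   `upper` (percentages, full precision).
#' @examples
#' prevalence(7718, 689301)
#' @export
prevalence <- function(n_cases, n_population, alpha = 0.05) {
  stopifnot(n_population > 0)
  if (n_cases > n_population) {
    stop("n_cases exceeds n_population", call. = FALSE)
  }
  ci <- clopper_pearson(n_cases, n_population, alpha)
  tibble::tibble(
    n_cases = as.integer(n_cases),
    n_population = as.integer(n_population),
    proportion = 100 * n_cases / n_population,
    lower = 100 * ci[[1]],
    upper = 100 * ci[[2]]
  )
}

#' Small-cell suppression for disclosure control
#'
#' Produces a reporting view of a confusion matrix in which cells below a
#' disclosure threshold are masked as `"<threshold>"`.  When exactly one
#' cell is masked, the smallest remaining cell is additionally masked as
#' `"suppressed"` (complementary suppression), so the masked value cannot be
#' recovered from published margins.  Metrics should always be computed from
#' the unmasked counts.
#'
#' @param cm A [confusion_matrix].
#' @param threshold Counts strictly below this are masked; 0 disables
#'   masking.
#' @return Named character vector with elements `tp`, `tn`, `fn`, `fp`.
#' @examples
#' suppress_small_cells(new_confusion_matrix(tp = 95, tn = 214,
#'                                           fp = 1, fn = 20))
#' @export
suppress_small_cells <- function(cm, threshold = 5) {
  stopifnot(inherits(cm, "confusion_matrix"), threshold >= 0)
  cells <- c(tp = cm$tp, tn = cm$tn, fn = cm$fn, fp = cm$fp)
  out <- stats::setNames(as.character(cells), names(cells))
  masked <- cells < threshold
  out[masked] <- paste0("<", threshold)
  if (sum(masked) == 1) {
    open <- which(!masked)
    complementary <- open[which.min(cells[open])]
    out[complementary] <- "suppressed"
  }
  out
}

#' Round half away from zero
#'
#' Reporting-style rounding (5 always rounds up in magnitude), as used when
#' comparing computed metrics to published 1-decimal tables; `base::round()`
#' rounds half to even instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @examples
#' round_half_up(82.55, 1)  # 82.6
#' round(82.55, 1)          # 82.5 under half-to-even
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @rdname round_half_up
#' @details `round_published()` reproduces the two-stage convention of the
#'   published validation tables, which report percentages first carried at
#'   two decimals and then transcribed at one: e.g. a sensitivity of
#'   3672/4033 = 91.049% prints as 91.1 (91.049 -> 91.05 -> 91.1), where
#'   single-stage rounding would give 91.0.  The two conventions agree on
#'   every published cell except those passing through an intermediate
#'   `.x45`-`.x5` window.
#' @export
round_published <- function(x) {
  round_half_up(round_half_up(x, 2), 1)
}
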