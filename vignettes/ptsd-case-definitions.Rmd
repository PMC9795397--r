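---
title: "Validating rule-based PTSD case definitions in primary care EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating rule-based PTSD case definitions in primary care EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsdemr)
```

## The problem

Posttraumatic stress disorder is hard to ascertain from routinely collected
primary care data.  The specific ICD-9-CM code (309.81) identifies it
directly, but not every record carries it: some jurisdictions' billing rules
only accept the 3-digit stem (309, "adjustment reaction", which is not
specific to PTSD), and providers often record the diagnosis only as free
text in the short diagnostic field ("PTSD", "p.t.s.d.", misspellings,
spelled-out phrases).  `ptsdemr` implements and validates four increasingly
elaborate boolean case definitions over a multi-table EMR extract of the
kind produced by practice-based research networks (a patient table plus
health condition, billing, encounter diagnosis and medication tables, each
row carrying a patient id, a date, a code and optionally a short diagnostic
text):

* **CD1** — ≥1 row with ICD-9-CM 309.81 in any of the three diagnosis
  tables;
* **CD2** — ≥1 *health condition* row with 309.81, or ≥2 billing/encounter
  rows with 309.81 separated by at least one week;
* **CD3** — CD2, or one billing/encounter 309.81 row together with a
  psychotropic medication (ATC code starting N05 or N06);
* **CD4** — CD1, or any row coded in the mental disorders chapter
  (ICD-9-CM 290–316) whose own diagnostic text names PTSD.

The clause structure nests the definitions: positives(CD2) ⊆
positives(CD3) ⊆ positives(CD1) ⊆ positives(CD4).  This is a theorem about
the rules, not a data property, and the test suite checks it on every
generated dataset.

## Text normalization

The short diagnostic text field names a diagnosis; it is not narrative
prose.  Normalization is therefore a pure string conversion: lower-case,
rewrite every lexicon variant to the canonical token `ptsd` (longest match
first, at word boundaries), strip characters outside `[a-z0-9 ]`, drop stop
words, tokenize.  Variant rewriting happens *before* punctuation stripping
so dotted acronyms ("P.T.S.D.") are still recognizable.  The shipped
variant list (`inst/extdata/ptsd_lexicon.txt`) covers the acronym, common
transpositions and the spelled-out phrases; it is a plain text file
precisely so that a list collected during an actual chart review can be
dropped in with `read_lexicon()`.  Two deliberate non-features:

* **No negation handling.**  "no ptsd" flags positive.  The conversion the
  definitions rely on is a keyword rewrite, and adding negation scoping
  would silently change what CD4 measures.
* **Field-level matching.**  Variants are replaced wherever they occur in
  the field, not per token; multiword phrases could not match otherwise.

An explicitly empty lexicon disables the text pathway entirely, which
reduces CD4 to CD1 exactly — a useful switch for isolating the contribution
of the text clause.

## Validation statistics

Agreement with a chart-review reference standard is summarized by the five
usual metrics of a 2×2 table — sensitivity, specificity, PPV, NPV, accuracy
— as percentages with two-sided confidence intervals.  Intervals are exact
binomial (Clopper–Pearson, from beta quantiles), the same family as the
exact binomial prevalence interval; a Wilson score interval is available as
`ci_method = "wilson"`.  Zero-denominator metrics are reported as `NA`,
never as zero.  Patients labeled "possible PTSD" by reviewers are excluded
before any counting.

Two reporting conventions matter when comparing against published tables:

* **Rounding.** `round_half_up()` rounds half away from zero at one
  decimal.  `round_published()` additionally reproduces the two-stage
  convention observable in the published validation tables this package
  ships as fixtures: percentages carried at two decimals, then transcribed
  at one.  The conventions differ only when a value passes through an
  intermediate `.x45–.x5` window (e.g. 91.049 → 91.05 → 91.1), and the
  fixtures contain two such cells; `reproduce_tables()` therefore compares
  with `round_published()`.
* **Small-cell suppression.** Cells below a disclosure threshold (default
  5) are masked as `<5`; when exactly one cell is masked, the smallest
  remaining cell is masked too ("complementary suppression"), otherwise the
  hidden value could be recovered from the published margins.  Metrics are
  always computed from unmasked counts.

The bundled fixtures (`published_confusions()`, `published_prevalence()`)
store the printed counts of a single-province free-text reference standard
(N=330), a single-province short-text reference standard (N=3212) and a
pan-Canadian short-text reference standard (N=12,104), plus three published
prevalence counts over 689,301 active patients.  For the free-text rows the
error cells were suppressed at publication, so only sensitivity and
specificity are recomputable from counts; `reproduce_tables()` validates
exactly those and recomputes everything for the fully printed rows:

```{r}
rep <- reproduce_tables()
attr(rep, "all_pass")
subset(as.data.frame(rep), reference_set == "pan-canadian" & definition == "cd4")
```

## The synthetic generator

Real chart-reviewed EMR extracts cannot be redistributed, so the package
carries a generator that emulates the *coding pathways* the definitions
exercise, with a known truth table.  Each patient is truly a case with
probability `prevalence` (default 0.014, placing the definition-based
prevalence in the 0.8–1.3% range typical of primary care populations).
Independently per case:

| pathway | parameter | default |
|---|---|---|
| health condition 309.81 row | `p_hc_specific` | 0.42 |
| each of `k_billing` = 2 billing 309.81 rows | `p_billing_specific` | 0.45 |
| jurisdiction truncates billing to 3 digits | `p_truncated_region` | 0.25 |
| PTSD mention on a mental-health-coded row | `p_text_mention` | 0.45 |
| mention uses a non-canonical variant | `misspelling_rate` | 0.30 |
| psychotropic (N05/N06) medication | `p_med_case` / `p_med_control` | 0.6 / 0.1 |
| related code (300/308/309/311) on a non-case | `p_related_codes_neg` | 0.30 |

Cases additionally receive one to three related mental-health encounter
rows; all dates are uniform over a three-year window.  Under independence
the expected CD1 sensitivity has the closed form

```
1 − (1 − p_hc) · (1 − (1 − p_trunc)(1 − (1 − p_bill)^k))
```

implemented as `expected_cd1_sensitivity()` and used as a
parameter-recovery target: at the defaults it equals 0.723, and the
empirical CD1 sensitivity on 50,000 simulated cases is required to land
within three binomial standard errors of it.  The defaults were chosen so
that the closed-form CD1 sensitivity sits near 72% and the text-supplemented
CD4 near 91%, mirroring the qualitative jurisdiction effect (truncated
billing lowers code-based capture while the text pathway survives); they
are illustrative operating points, not fitted estimates.

The simulated dual review labels every patient twice, each reviewer
flipping the truth with probability `reviewer_error` (default 0.05);
agreements stand, disagreements are adjudicated to the truth with
probability `p_adjudicate` (default 0.9) and otherwise become
"possible PTSD" (excluded downstream).  Disagreement occurs with
probability `2e(1−e)`, which the tests verify at the configured rates.

What the generator deliberately does **not** model: comorbidity structure,
visit-frequency patterns, demographic confounding, free-text encounter
notes, and any miscoding of non-cases with 309.81 — so generated
specificities are 1 by construction and the published false-positive
counts cannot be reproduced from simulation (they enter only through the
printed fixtures).  Passing tests on synthetic data therefore demonstrate
that the machinery is correct under the stated generative model, not that
the definitions achieve any particular operating point on real data.
An enrichment-sampling switch for reference-set construction is likewise
out of scope: the published reference sets were sampled conditionally on
related codes, so their PPV/NPV are set-specific, and the sampling
fractions needed to emulate that are not published.

## Numerical and design choices

* ICD-9-CM codes are compared after normalization (strip dots and
  whitespace, upper-case), so `"309.81"` and `"30981"` are identical;
  V- and E-prefixed codes have no numeric stem and never match a numeric
  chapter range.
* "Separated by at least 1 week" is a date difference ≥ 7 days, inclusive;
  duplicate same-day rows never satisfy the pair clause (separation 0).
  Setting `min_separation_days = 0` intentionally degenerates the clause
  to "any two rows".
* CD3's medication clause requires no temporal link between the diagnosis
  row and the prescription; none is stated for the rule and imposing a
  window would only lower sensitivity unverifiably.
* CD4 pairs the text mention with the in-chapter code *on the same row* by
  default (the code recorded for that encounter);
  `patient_level_text = TRUE` relaxes this to patient-level pairing.
* The activity window for prevalence denominators is a parameter
  (`index_date`, `window_years`, default 2 years) rather than a constant,
  because published descriptions of "active patient" windows are often
  internally inconsistent; the denominator is whoever last attended within
  the window, both endpoints inclusive.
* The acceptance checks and examples run at moderate sizes (50,000
  simulated cases for parameter recovery, cohorts of a few thousand
  elsewhere), sizes at which the binomial bounds used by the tests are
  already tight.

## Limitations

The package validates *diagnosed, documented* PTSD as a rule over codes,
dates, medications and short text.  It does not attempt symptom-level
phenotyping, encounter-note NLP, or machine-learned classification, and a
definition validated against one network's coding culture will not
automatically transfer to another — which is exactly the question the
agreement statistics are designed to answer.
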