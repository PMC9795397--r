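# ptsdemr

Rule-based posttraumatic stress disorder (PTSD) case definitions for
multi-table primary care electronic medical record (EMR) extracts, with the
agreement statistics needed to validate them against chart-review reference
standards.

EMR phenotyping for PTSD is awkward: the specific ICD-9-CM code 309.81
identifies it directly, but some jurisdictions' billing rules truncate
codes to the 3-digit stem (309, "adjustment reaction", not PTSD-specific),
and providers often record the diagnosis only in the short diagnostic text
field — as "PTSD", a dotted acronym, or a misspelling.  `ptsdemr`
implements four nested boolean case definitions over the health condition,
billing, encounter diagnosis and medication tables:

| | rule |
|---|---|
| CD1 | ≥1 row with ICD-9-CM 309.81 in any diagnosis table |
| CD2 | ≥1 health-condition 309.81 row, OR ≥2 billing/encounter 309.81 rows ≥1 week apart |
| CD3 | CD2, OR a billing/encounter 309.81 row plus an ATC N05/N06 medication |
| CD4 | CD1, OR any ICD-9-CM 290–316 row whose own short text names PTSD (lexicon-based) |

Around the definitions the package provides:

* a validated data model and CSV reader/writer for the five-table extract;
* short-text normalization with an editable variant lexicon
  (`inst/extdata/ptsd_lexicon.txt`) rewriting acronyms, misspellings and
  spelled-out phrases to a canonical token;
* agreement statistics — sensitivity, specificity, PPV, NPV, accuracy —
  with exact binomial (Clopper–Pearson) confidence intervals
  (`sens = TP/(TP+FN)`, `spec = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
  `NPV = TN/(TN+FN)`, `acc = (TP+TN)/N`), exact binomial prevalence, and
  small-cell suppression for disclosure control;
* a synthetic EMR generator with known truth and a simulated dual-reviewer
  labeling process (with adjudication and "possible PTSD" exclusion), so
  the whole pipeline is testable without patient data;
* bundled published validation fixtures and `reproduce_tables()` to
  recompute them.

See `vignettes/ptsd-case-definitions.Rmd` for the model, parameter and
design details.

## Worked example

Score a published pan-Canadian confusion matrix (text-supplemented
definition CD4; TP 3672, TN 8000, FP 71, FN 361):

```r
library(ptsdemr)
cm <- new_confusion_matrix(tp = 3672, tn = 8000, fp = 71, fn = 361)
agreement_metrics(cm)
#> # A tibble: 5 × 6
#>   metric      numerator denominator estimate lower upper
#>   <chr>           <int>       <int>    <dbl> <dbl> <dbl>
#> 1 sensitivity      3672        4033     91.0  90.1  91.9
#> 2 specificity      8000        8071     99.1  98.9  99.3
#> 3 ppv              3672        3743     98.1  97.6  98.5
#> 4 npv              8000        8361     95.7  95.2  96.1
#> 5 accuracy        11672       12104     96.4  96.1  96.8
```

The estimates are percentages with exact 95% intervals: the definition
captures 91.0% of reference-standard cases and 96.4% of all calls agree
with the reviewers.

End-to-end on a synthetic cohort — generate 10,000 patients, simulate dual
chart review, classify with all four definitions, validate and estimate
prevalence among patients active in the last two years:

```r
report <- run_pipeline(synthetic_config(n_patients = 10000, seed = 2026))
report
#> <ptsd_pipeline_report>
#>  CD1: sensitivity 63.8 (55.8-71.2), specificity 100 (100-100), ppv 100 (96.4-100), npv 99.4 (99.2-99.5), accuracy 99.4 (99.2-99.6)
#>  CD2: sensitivity 43.1 (35.3-51.2), specificity 100 (100-100), ppv 100 (94.8-100), npv 99.1 (98.9-99.3), accuracy 99.1 (98.9-99.3)
#>  CD3: sensitivity 56.3 (48.2-64.1), specificity 100 (100-100), ppv 100 (96-100), npv 99.3 (99.1-99.4), accuracy 99.3 (99.1-99.4)
#>  CD4: sensitivity 75.6 (68.2-82.1), specificity 100 (100-100), ppv 100 (97-100), npv 99.6 (99.5-99.7), accuracy 99.6 (99.5-99.7)
#>   prevalence (% of 7434 active patients):
#>     CD1: 1.37 (1.12-1.66), n=102
#>     CD2: 0.94 (0.73-1.19), n=70
#>     CD3: 1.22 (0.99-1.50), n=91
#>     CD4: 1.63 (1.35-1.94), n=121
```

The sensitivity ordering CD2 ≤ CD3 ≤ CD1 ≤ CD4 is forced by the nesting of
the rules; the noisy simulated review (5% per-reviewer error) is why even
CD4 scores well below 100% against the labels.  A command-line front end
over the same functions (verbs `generate`, `classify`, `validate`,
`prevalence`, `run`, `reproduce-tables`) is in
`inst/scripts/ptsdemr-cli.R`.

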