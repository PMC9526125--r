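# cmrextract

Quantitative cardiac MRI (CMR) measurements — ventricular volumes, ejection
fractions, myocardial mass, vessel dimensions — are locked inside free-text
diagnostic reports in most electronic health records. **cmrextract** is an R
package for clinical-NLP and cardiology researchers that turns such reports
into a structured measurement table with a small annotation budget, and
validates the extractions against clinical outcomes.

The core is token classification: a report is subword-tokenized and a
transformer encoder with a linear head assigns each token a label from a
22-label space (21 CMR measurements + a null label `0`). For a token *t* with
encoder state *h_t*, the head produces *p(y | t) = softmax(W h_t + b)*; a
label is assigned when its score exceeds 0.5 (evaluation rule) or by argmax
(at-scale rule). Contiguous same-label runs are consolidated into spans,
mapped back to the original text through exact offset maps, parsed into
numeric values, and filtered against physiologic reference ranges.
Performance is summarized by the macro-averaged F1 over the 21 measurement
labels with report-level bootstrap CIs. Five numerical token representations
(original, `51|01`, `051010`, `5.10100e+01`, "fifty one point zero one") are
implemented with exact inverse parsing. An outcome module computes incidence
rates per 100 person-years with exact (Garwood) Poisson intervals, two-sample
rate comparisons, quartile and threshold stratification (abnormal LVEF < 50%,
RVEF < 45%), and earliest/latest-report feature selection.

Because clinical reports cannot be shared, the package includes a seeded
synthetic CMR-report generator (layout styles, alias variation, optional
units, distractor numbers, gold standoff annotations) so that the entire
workflow — generate → transform → tokenize → train → predict → consolidate →
evaluate / outcomes — runs end-to-end out of the box.

## Worked example

```r
library(cmrextract)

schema <- default_schema()          # 21 measurements + null = 22 labels
n_labels(schema)
#> [1] 22

# the numerical representations, on the reference snippet
transform_text("RVESV: 51.01 ml", "replaced_decimal")$text
#> [1] "RVESV: 51|01 ml"
transform_text("RVESV: 51.01 ml", "consistent_digits")$text
#> [1] "RVESV: 051010 ml"
invert_value("051010", "consistent_digits")
#> [1] 51.01

# an end-to-end run on synthetic reports (about 4 minutes on one CPU)
res <- run_end_to_end(run_config(
  n_train = 200, n_test = 100,
  train = train_config(batch_size = 4, max_epochs = 40, dropout = 0.05, seed = 1),
  seed = 1))
res$metrics$macro_f1        # held-out token-level macro-F1
#> [1] 0.978
head(emitted_measurements(res$measurements), 4)
#> # A tibble: 4 × 6
#>   report_id label  value start   end score
#>   <chr>     <chr>  <dbl> <int> <int> <dbl>
#> 1 R00001    lvedvi  61      15    17 0.986
#> 2 R00001    lvm     56.2    41    45 0.959
#> 3 R00001    co       7.8    70    73 0.996
#> 4 R00001    lvmi    53      86    88 0.984

# outcome statistics
rate <- incidence_rate(10, 500)     # 10 events over 500 person-years
rate
#> # A tibble: 1 × 5
#>   events person_years  rate    lo    hi
#>    <int>        <dbl> <dbl> <dbl> <dbl>
#> 1     10          500     2 0.959  3.68
```

`incidence_rate(10, 500)` prints a rate of 2.0 events per 100 person-years
with the exact 95% interval (0.96, 3.68) from the chi-square form of the
Poisson bounds. In the end-to-end run, the from-scratch encoder reaches a
held-out macro-F1 of 0.978 (the unweighted mean of per-measurement token F1
over the 21 measurements, best epoch selected on the evaluation split), and
`emitted_measurements()` is the final structured table — 1058 extracted
measurements over the 100 test reports, one row per report × measurement with
value, source span and score.

A thin command-line wrapper over the same functions ships in
`inst/cli/cmrextract.R` (subcommands `generate`, `transform`, `run`, `grid`,
`agreement`).

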