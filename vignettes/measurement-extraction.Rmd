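---
title: "Extracting quantitative measurements from cardiac MRI reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting quantitative measurements from cardiac MRI reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac magnetic resonance (CMR) reports carry the definitive quantitative
assessment of cardiac anatomy and function — ventricular volumes, ejection
fractions, myocardial mass, vessel dimensions — but in most electronic health
records they exist only as free text. The same measurement appears under many
surface names ("LVEF", "LV ejection fraction"), with or without units, as an
integer or with decimals, in narrative sentences, colon-separated lists or
dense tabular lines, surrounded by distractor numbers (dates, heart rates,
slice thickness). **cmrextract** implements a label-efficient workflow for
turning such reports into a structured measurement table: token-level sequence
labeling with a transformer encoder over a 22-label space (21 measurements
plus a null label), followed by span consolidation, value parsing and
physiologic filtering, and a set of incidence-rate statistics for validating
extractions against clinical outcomes.

## Token classification model

Reports are subword-tokenized with exact character offsets, gold standoff
annotations are projected onto tokens by span overlap (every piece of `51.01`
— `51`, `.`, `01` — carries the annotation's label), and token sequences are
cut into windows of at most 128 tokens; a window boundary prefers the last
line or sentence break inside the window and never splits an annotation run,
so windowing is lossless. The classifier is a compact transformer encoder with a
linear head producing a per-token distribution over the 22 labels, trained
with masked cross-entropy. Two decoding rules are provided: *threshold*
decoding assigns a label only when its score exceeds 0.5 (with normalized
scores at most one label can), abstaining to null otherwise — this is the rule
used for evaluation — and *argmax* decoding, used when applying a trained
model at scale.

### The from-scratch encoder profile

The package's reference profile, `tiny_scratch`, is a 2-layer, 128-hidden,
4-head pre-layer-norm encoder trained from random initialization, so the full
workflow runs end-to-end with no model download. Three design choices matter
and were made once, on the training dynamics of the synthetic task:

* **Relative position via directional attention biases.** Positional
  information enters as a fixed per-head linear distance penalty on attention
  logits (in the attention-with-linear-biases family), and the penalty is
  *directional*: half the heads penalize following context steeply and
  preceding context gently — measurement names precede their values in
  report layouts — while the rest range from symmetric-local to near-global.
  Learned absolute position embeddings let a small model memorize *where* in
  a specific training window each value sat (observed as near-perfect
  training F1 with poor held-out F1); the translation-invariant, look-left
  penalty forces it to learn the local name–value relationship, which is what
  generalizes across layouts.
* **Pre-layer-norm blocks.** With normalization inside the residual branch
  (and a final normalization before the head) the encoder trains stably at
  practical learning rates from random initialization, without a warmup
  schedule.
* **Shape-embedded digits.** The tokenizer keeps every digit piece's text and
  offsets but maps digit pieces to shared per-shape embedding ids: distinct
  ids per digit string invite memorizing accidental digit–label correlations
  in a small corpus, while the information that actually identifies a
  measurement lives in the surrounding words.
* **Regularization and averaging.** Decoupled weight decay (0.01), residual
  dropout, and an exponential moving average of the parameters (decay 0.998)
  evaluated at each epoch counteract memorization and small-batch noise.
* **Boundary-aware windows.** Training/evaluation windows prefer to cut at
  the last line or sentence boundary inside the window, so a hard cut cannot
  strand a value at a window start away from its measurement name.

Fine-tuning a pretrained encoder — the setting the workflow is designed
around in production — uses learning rate 5e-5, batch size 32 and up to 20
epochs, with per-epoch metrics returned so the caller can select the epoch
maximizing macro-averaged F1. A randomly initialized encoder does not move at
a fine-tuning rate, so the `tiny_scratch` profile defaults to 1e-3. Adam uses
a linear learning-rate decay by default (the usual fine-tuning schedule); the
from-scratch acceptance recipe keeps the rate fixed. Per-epoch dev evaluation
uses threshold decoding;
the best epoch's parameters are kept. Model selection on the *test* set
reproduces the original protocol exactly but conflates selection with
evaluation; passing a separate dev split avoids the leakage, and both are
possible since the evaluation set is an argument.

## Numerical representations

Subword vocabularies fragment decimal numbers, so five representations of
numeric tokens are implemented, each with an exact invertible offset map back
to the original text:

| mode | `51.01` becomes | notes |
|---|---|---|
| `original` | `51.01` | identity |
| `replaced_decimal` | `51\|01` | `\|` registered as a special token so the number stays one token |
| `consistent_digits` | `051010` | always 6 digits: 3 integer + 3 fractional, zero-padded; values ≥ 1000 or negative are not representable and pass through with a warning record |
| `scientific` | `5.10100e+01` | 6-digit mantissa, matching the reference rendering (a 5-significant-digit reading would print `5.1010e+01`; the printed example is taken as normative) |
| `words` | `fifty one point zero one` | lowercase, tens-units unhyphenated, decimals digit-by-digit |

Numeric tokens are maximal signed digit runs with at most one decimal point,
delimited by non-alphanumerics; range components (`55-60`), fractions and
slashed dates pass through untransformed. Inversion is exact for
`replaced_decimal` and `scientific` and exact to 3 decimals for
`consistent_digits` and `words`.

## Postprocessing

Maximal same-label token runs become candidate spans; each is mapped to
original-text coordinates through the offset map, extended over missed
significant digits (`merge_digits()` grows a run across adjacent digits and an
interior decimal point, never across whitespace), and parsed. Per report and
label, the candidate with the highest mean token score is emitted; duplicates
and non-parseable candidates are retained with flags, so candidates are
conserved. Physiologic filtering flags values strictly outside each
measurement's reference range — bounds are packaged configuration
(literature-typical values, editable in the schema JSON), not model logic.

## Synthetic corpus: what it emulates, and what it does not

Clinical reports cannot be shared, so the package ships a seeded generator
whose reports emulate the documented variability of CMR text: three layout
styles (narrative / colon list / tabular), 1–21 measurements per report in
random order, ≥ 3 surface aliases per measurement, units present or absent
(always absent in tabular lines), integer/1-dp/2-dp value formatting, and
distractor sentences with numbers that belong to no measurement. Values are
sampled uniformly within each measurement's physiologic range (the source
material gives no value distributions), with an optional `out_of_range_rate`
mass placed just outside the bounds to exercise the filter; the default rate
is 0.02, and corpora meant to validate gold-pass-through identities use 0 so
that filtering is a no-op by construction. Defaults were chosen once:
inclusion probability 0.5 per measurement (true per-measurement frequencies
are not public), ~2 distractors per report.

The generator is templated text. It does not emulate institution headers,
negation ("LVEF could not be assessed"), free-text hedging, cross-measurement
arithmetic consistency (EF vs volumes), typos, or vocabulary drift between
sites. A model that is perfect here can still fail on real reports; passing
tests demonstrate the correctness of the pipeline machinery and the
learnability of the name–value structure, not clinical performance.

## Evaluation

Token-level precision/recall/F1 per measurement; the headline metric is the
unweighted (macro) mean of per-label F1 over the 21 measurement labels — never
the null label — with labels absent from both gold and predictions excluded
(inclusion-as-zero is available behind a flag). Bootstrap confidence intervals
resample whole reports (not tokens), respecting within-report correlation,
with B = 1000 by default. One-vs-rest ROC curves and AUC per measurement are
computed from token scores (via pROC). The learning-curve experiment draws
nested training subsets once per seed and reports, per size, the maximum
macro-F1 over epochs on a fixed evaluation set.

At desk scale the acceptance surface is parameter recovery on synthetic data:
the `tiny_scratch` profile trained on 200 synthetic reports (batch 4, fixed
learning rate 1e-3, weight decay 0.01, dropout 0.05, 40 epochs) is expected to
reach macro-F1 ≥ 0.90 on 100 held-out synthetic reports, and the learning
curve over sizes 25/100/200 to be non-decreasing within noise 0.05. Problem
sizes (200/100 reports, 2-layer encoder, 40 epochs) were chosen as the
smallest at which recovery is stable; small batches buy more optimization
steps per epoch at the same cost, which is what a from-scratch encoder is
short of.

## Outcome validation statistics

To validate extractions against clinical outcomes the package implements the
person-time machinery used in the source analyses: follow-up from the CMR
date to the earliest of outcome, death, or last encounter (prevalent cases
excluded upstream); incidence rates per 100 person-years with the exact
(Garwood) chi-square interval — `qchisq(α/2, 2k)/2` to
`qchisq(1-α/2, 2k+2)/2` scaled by person-time — which is the standard exact
method for person-time rates; a two-sample test of proportions applied to
rates through a pooled-variance z statistic (the phrase is ambiguous for
person-time data; the pooled-rate z form is documented and swappable);
quartile stratification with inclusive type-7 quantiles and ties to the lower
stratum; threshold rules that are strict inequalities (abnormal LVEF < 50%,
abnormal RVEF < 45%); and earliest-report (primary) or latest-report
(sensitivity) selection per person with id tie-breaks. A seeded cohort
simulator with exponential event/death times and uniform censoring provides
the test bed; exact-CI coverage is validated by simulation against the
nominal 95%.

## Numerical and degenerate-input choices

* Layer norm ε = 1e-5; cross-entropy clamps log arguments at 1e-12; scores are
  softmax rows summing to 1 within 1e-6.
* Argmax ties break to the lowest label index; uniform scores decode to the
  null label under thresholding.
* Empty agreement unions are defined as agreement 1; single-report bootstraps
  warn and return a degenerate interval; zero-event rates have exact lower
  bound 0.
* Batches bucket windows of similar length (the batch order, not composition,
  is reshuffled per epoch) — a throughput choice that also makes training
  deterministic given the seed.
* Windows at inference are cut at exactly `max_len` with a 16-token overlap;
  a twice-covered token takes its prediction from the window where it is more
  interior.

## Known limitations

The from-scratch profile is a study vehicle: on real clinical text a
pretrained clinical or general-domain encoder (the production setting) is
expected to dominate it, and nothing here measures that gap. The generator's
simplifications listed above bound what synthetic results can claim. The
tokenizer is a compact longest-match subword scheme, not a trained BPE/WordPiece
vocabulary; any offsets-preserving tokenizer can be injected in its place.
Unit conversion between reporting conventions is out of scope — values are
taken as printed.
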