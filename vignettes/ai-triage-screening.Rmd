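---
title: "Simulating AI triage in a mammography screening program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AI triage in a mammography screening program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentriage)
```

## The problem

Population mammography screening programs with double reading face a
workload problem: two radiologists read every mammogram, almost all of
which are negative. Commercial AI systems assign each mammogram a
malignancy risk score in \[0, 100\] (the maximum over both breasts), which
raises a policy question: can the score *triage* mammograms — auto-clearing
the lowest-risk exams and concentrating human reading on the rest — without
losing cancers that double reading would have caught?

`screentriage` implements the analysis pipeline for that question on a
per-visit table of screening mammograms (woman, month-resolution visit
date, AI score, BI-RADS assessment, recorded double-reading outcome,
histology-confirmed cancer status and detection mode). Five stages compose
on that table; each is usable on its own.

## Triage model

A visit with score $s$ is assigned one of three categories at cut points
$(c_\ell, c_h)$:

* **green** if $s \le c_\ell$ — auto-negative, eliminated from reading;
* **red** if $s \ge c_h$ — positive, escalated;
* **yellow** otherwise — flagged for human review.

The low cut defaults to 1 because the scoring software itself reports
scores below 1 as low risk. Both boundary conventions matter: the score
exactly at the threshold is red (test-positivity is $s \ge c_h$
throughout, including in the ROC machinery), and the score exactly at the
low cut is green. No observed score sits exactly at 1 in any packaged
fixture, so the choice between "below 1" and "at or below 1" does not move
any packaged number; we fix $\le$ once and use it everywhere.

`operating_metrics()` treats red as the positive call: sensitivity is the
red share of cancers, and — deliberately — *flagged cancers count as false
negatives of the positive call* (`fn_rate_cancer` is the green + yellow
share). The per-detection-mode rates are red shares within screen-detected,
interval and missed cancers.

## Threshold selection

`build_roc()` uses every distinct observed score as a candidate threshold
(plus one sentinel above the maximum), so maximization is exact with no
discretization error. `roc_auc()` is the trapezoidal area, which on this
threshold set equals the Mann–Whitney concordance probability with ties
counted half — the test suite checks that identity against an all-pairs
oracle at $10^{-12}$ on instances up to 200 points, and against `pROC` as
an independent library. `youden_threshold()` maximizes
$J = \text{sens} + \text{spec} - 1$; ties within $10^{-12}$ break toward
the *lowest* qualifying threshold, favouring sensitivity as appropriate in
screening, and the tie-break is surfaced in the result. The AUC confidence
interval is a percentile bootstrap (the method is otherwise unspecified in
the source material); single-class replicates are redrawn and counted.

## Prevalence-matched bootstrap

The retrieved study sample is cancer-enriched relative to the program it
came from, so workflow simulation runs on a *simulated data set*: all
cancer visits are kept, and non-cancer visits are resampled with
replacement until the cohort reaches a target cancer rate $r$ (default
5.7 per 1000 mammograms). The cohort size is
$\mathrm{round}(n_{\text{cancer}} / r)$ — 105 cancers at 0.0057 give
18,421 mammograms, hence 18,316 non-cancer draws per iteration.
Resampling is at the visit level (the unit the rate is defined on); a
woman-level option resamples whole women and trims the final block.
`bootstrap_cohorts()` streams iterations through a callback so memory is
constant in the iteration count, and `simulate_scenarios()` uses an
index-resampling fast path: a drawn non-cancer visit is fully described by
its (triage category × recorded recall) cell, so per-iteration accounting
reduces to a 6-cell tabulation and 10,000 iterations run in seconds.

## Reading workflows

Four scenarios are accounted per cohort:

| scenario | human reads per visit | cancer detected when |
|---|---|---|
| `bmsp` | 2 | recorded double-reading outcome |
| `s1`   | 1 | recorded outcome **or** AI red |
| `s2`   | 1 + 1 per yellow | s1 rule **or** second reader on yellow |
| `s3`   | 0 green, 1 yellow/red | triage reader's call on yellow/red |

Third-reader arbitration in `bmsp` is noted but excluded from workload
(the baseline is exactly two reads per mammogram). The scenarios
presuppose human behaviour the source data cannot identify, so the reader
model for the AI-era stages (the second reader on yellows in `s2`, the
single triage reader in `s3`) is explicit:

* `flag_perfect` (default): the human detects every cancer the AI flagged
  yellow or red; non-cancer recalls follow the recorded labels. On the
  packaged fixture this reproduces the reference results (100 detected / 5
  missed under `s3`; 101 / 4 under `s2`).
* `observed` (conservative): the human repeats the recorded double-reading
  outcome.

Under `s1` the fixture yields 87 detected — the union of 68 recorded
detections and 76 red cancers. No reader assumption we could state turns
that union into fewer detections without also changing `s2`/`s3`, so the
package reports 87 rather than silently tuning a single-reader sensitivity;
the discrepancy with external figures is documented here and in the test
suite rather than hidden.

Recalls (the PPV1 denominator) are the visits called positive by the final
workflow decision: recorded recalls on humanly read visits, plus AI-red
escalation where the scenario eliminates or triages reads. This definition
is stated because it is not derivable from the source material; NPV and
PPV1 therefore depend on it and on the fixture's lack of non-cancer recall
information, and are reported but not treated as reference values.

## Lead-time analysis

For each cancer patient, `earliest_positive_prior()` returns the whole
months between the diagnosis visit and the *earliest* prior visit scoring
at or above the threshold (a latest-prior variant exists behind a flag).
Using the earliest prior maximizes the potential gain and matches the
per-patient year counts the analysis reproduces. `lead_time_summary()`
aggregates patients, counts AI-positive prior mammograms separately from
patients, and bins exact month differences to the nearest reporting bin
(6/12/24/36/48/72 months) while always retaining the raw months. On the
packaged longitudinal fixture the bins give a mean of 29.25 months over 24
patients; the fixture's per-visit dates beyond the binned lead times are
synthetic allocations consistent with the printed margins, so patient and
mammogram counts — not the mean — are the meaningful checks.

## The synthetic cohort generator

`generate_cohort()` exists so every downstream stage is testable at scale
without any external data. Its defaults are fixed to the study conditions:
biennial (24-month) rounds, five rounds, a per-mammogram cancer rate of
0.0057, AI-score category masses equal to the published contingency
proportions for each truth class, detection-mode composition
(68, 29, 8)/105, a 24/105 prior-positive fraction with lead times drawn
from the published bins. Within each triage segment the score density is
uniform — the least-informative choice consistent with category masses,
which keeps the Youden optimum identifiable at the configured cut. Two
quantities the source material does not state are fixed once here: the
non-cancer recall rate (0.05, a typical European screening recall figure)
and the interval-cancer diagnosis delay (uniform over 1–24 months after
the negative visit; missed cancers at 1 month).

Design notes worth knowing:

* Cancer is assigned per visit at the configured rate; a woman has at most
  one cancer episode and leaves the program once diagnosed.
* Prior-positive lead times are honoured *exactly*: when the drawn lead is
  a multiple of the screening interval the existing grid visit's score is
  elevated into the red segment, otherwise an extra off-grid visit is
  inserted at that month. Regular visits remain 24 months apart;
  inserted priors are the only off-grid rows.
* Sampling uses one root seed with deterministic per-component sub-seeds
  (cohort structure, scores, detection modes, priors), so stages can be
  regenerated and tested independently and identical configs give
  byte-identical cohorts.

What the generator does **not** emulate: tumour growth, radiologist
variability beyond the configured labels, correlation of a woman's scores
across visits (other than the designed prior positives), score densities
within categories, or calendar effects. Tests that pass on synthetic
cohorts therefore demonstrate the *accounting machinery* — category
recovery, conservation, bootstrap expectations — not fidelity to any real
score distribution.

## Numerical choices and degenerate inputs

* Cohort-size rounding is to the nearest integer (105/0.0057 = 18,421.05
  → 18,421).
* ROC requires both classes; single-class inputs raise a classed
  degenerate-input error rather than returning NaN curves.
* Zero-denominator metrics (no recalls, no negatives, empty truth class)
  raise classed metric errors.
* Probability vectors must sum to 1 within $10^{-9}$; zero-width score
  segments are configuration errors.
* Bootstrap aggregation reports means and percentile intervals; the single
  printed realization of the reference analysis is treated as one draw
  from that distribution.

## Problem sizes

The shipped analyses are desk-scale by design: the fixture table has 4,998
rows; scenario bootstraps use 10,000 iterations (seconds via the fast
path); the distributional recovery checks in the test suite use cohorts of
50,000–100,000 sampled scores and a few hundred bootstrap iterations,
with tolerances stated as 3 standard errors of the relevant estimator.

## A worked run

```{r example, eval = FALSE}
fixture <- expand_table2_visits()                 # 4,998 visits
operating_metrics(build_triage_table(fixture))    # sens 72.38%, FP 7.13%

res <- simulate_scenarios(fixture, rate = 0.0057, n_iter = 10000, seed = 1)
res[, c("scenario", "detected", "workload_mean",
        "workload_reduction_vs_bmsp")]

lead_time_summary(leadtime_fixture_cohort())      # 24 patients, 35 priors
```

## Known limitations

* The packaged fixture carries category-level information only; any
  statistic that needs within-category score variation (the AUC above all)
  is not reproducible from it and is not claimed.
* Reader models are deterministic policies; inter-reader variability and
  arbitration are out of scope.
* Lead-time fixtures reproduce printed margins, not actual visit spacing;
  the mean lead time on real data need not equal the binned mean.
* The pipeline treats scores as given — the scoring model itself is an
  input, never computed.
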