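---
title: "Pig-specific sepsis severity scoring: models, thresholds, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pig-specific sepsis severity scoring: models, thresholds, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinescore)
```

## The problem

Clinical sepsis scores — SIRS, SOFA and NEWS2 — are defined for humans.
Applying them to a conscious porcine trauma model requires species-specific
thresholds, because a healthy Yorkshire pig's heart rate, respiration rate
and temperature differ from a human's and oscillate with the facility's
12-h light cycle. `swinescore` implements the full analysis chain for such
a model: it derives pig-specific SIRS thresholds and NEWS2 bands from
healthy-baseline telemetry, scores animals with SIRS, an adapted six-system
SOFA (whose neurological component is the SNORT observer rubric), and
NEWS2, aggregates scores over a 72-h observation period into prevalence
tables with death censoring, compares groups with an exact Mann-Whitney
test under Holm-Sidak correction, and classifies animals by a deterministic
rule set. Because no animal-level dataset is publicly deposited, the
package ships a first-class synthetic cohort generator whose defaults
emulate the statistical structure of a penetrating-abdominal-trauma (PAT)
fecal-peritonitis model with a sham-surgery control group.

## Threshold derivation

Thresholds come from the diurnal statistics of a healthy baseline window:
the 48 h of telemetry immediately preceding the morning baseline blood
draw (configurable via `window_start`/`window_end`). Each sample is
assigned to the day phase when its clock time satisfies
`lights_on <= clock < lights_off` (default 06:00-18:00), and per-parameter,
per-phase means and sample SDs (n − 1 denominator, the default of common
statistics software) are computed. WBC comes from the blood draws in the
same window, pooled without a diurnal split, because the draws are 8 h
apart and carry no day/night structure.

* **SIRS**: a parameter's criterion bounds are `mean ± 2 SD`, rounded to
  its display precision (integer bpm/mmHg, 0.1 °C, 0.1 × 10³/µL) with
  half-away-from-zero rounding (`round_half_away()`), which matches the
  published tables (130.2 → 130, 69.8 → 70, 39.88 → 39.9, 84.9 → 85). A
  criterion is *met* when a value lies strictly outside the rounded
  bounds; the SIRS state requires at least two of the four criteria (heart
  rate, respiration rate, temperature, WBC).
* **NEWS2**: band edges sit at `mean ± {1, 2, 3, 4} SD`, rounded the same
  way. The closed 0-point band is `[mean − 1 SD, mean + 1 SD]`; the ±2,
  ±3 and ±4 SD edges are inclusive outer boundaries of the 1-, 2- and
  3-point bands on each side. Values in the open gap between the 0-band
  and a ±2 SD edge score 0 — the published table prints those regions
  blank, and assigning them the milder score is the conservative reading
  consistent with every printed column (e.g. a nighttime heart rate of
  116 bpm, exactly mean + 2 SD, prints in the 1-point column). Two NEWS2
  rows are absolute human-derived cut-offs rather than derived: SpO₂
  (≥96 → 0, 94–95 → 1, 92–93 → 2, ≤91 → 3) and SNORT (≥10 → 0,
  <10 → 3). A parameter in any 3-point band raises the *extreme* flag,
  and a score is positive when the total reaches 5 or any extreme flag is
  set.

### The derived-vs-printed audit

A handful of published threshold cells are inconsistent with the
`mean ± k SD` arithmetic on the published (rounded) means by one display
unit — e.g. the respiration-rate upper SIRS bounds, the WBC upper bound,
and several temperature and daytime systolic-pressure NEWS2 cells. The
package treats the printed means/SDs as the inputs and does **not**
reverse-engineer unrounded means; `audit_sirs_table()` and
`audit_news2_table()` compare every derived cell against the printed
tables (`printed_sirs_table()`, `printed_news2_table()`) and flag the
mismatches instead of silently matching them:

```{r audit}
st <- printed_baseline_stats()
a <- audit_sirs_table(derive_sirs_table(st))
a[!is.na(a$match) & !a$match, ]
```

Systolic blood pressure appears in the NEWS2 table but its baseline mean
and SD are not published anywhere; `printed_baseline_stats()` reconstructs
them from the printed 0-point bands (day 126–154 → mean 140, SD 14; night
120–145 → mean 132.5, SD 12.5) and labels the object accordingly. The
night row reproduces every printed cell; the day row's lower cells print
one unit higher than the arithmetic and are audit-flagged.

## Scoring engines

`sofa_component()` encodes the adapted six-system table with the interval
conventions of the printed bands: the respiratory chain is half-open
descending on the P/F ratio (≥400 → 0, <400 → 1, <300 → 2, <200 → 3,
<100 → 4); the hematological chain has closed upper edges on platelets
(≤150 → 1, ≤100 → 2, ≤50 → 3, ≤20 → 4); creatinine and bilirubin are
rounded to one decimal before closed-interval lookup so the printed gaps
(e.g. 1.4–1.5 mg/dL) cannot be hit; MAP is rounded to an integer and
70 mmHg itself scores 1 (the printed bands are ">70" and "60–70"); SNORT
maps [10, 11] → 0, [8, 10) → 1, [6, 8) → 2, [4, 6) → 3, [2, 4) → 4,
accepting fractional inputs because group medians (e.g. 6.6) are
routinely fractional. Values below the lowest defined renal/hepatic band
(a healthy pig's bilirubin of 0.11 mg/dL is below the 0.3–0.6 0-band)
score 0 with an out-of-table note. Sepsis is indicated by a SOFA total at
least 2 above the animal's baseline total; the pipeline anchors that
baseline at each animal's pre-injury (time 0) total, the only defensible
anchor when the baseline is otherwise unspecified.

Missing values are first-class: SIRS reports unknown criteria and counts
`n_met` over the known ones; SOFA marks partial totals and leaves the
sepsis flag undefined unless the partial total already clears the rule;
NEWS2 scores missing parameters (typically SpO₂ and systolic pressure in
telemetry-only snapshots) as 0 points and records them in a completeness
field — penalizing missingness would fabricate signal.

## Group comparison

Score data are ordinal, so groups are compared per timepoint with a
Mann-Whitney test whose two-sided p value is computed *exactly* by
enumerating all `choose(n, n_A)` assignments of the observed mid-ranks
(ties handled by the exact conditional distribution). At the study's group
sizes (4 + 8) that is 495 assignments; complete separation gives
p = 2/495 ≈ 0.004, the smallest attainable two-sided value. Above 14
total observations the implementation falls back to a seeded Monte-Carlo
permutation approximation. Raw p values across timepoints are adjusted
with the Holm-Sidak step-down method
(`adj_i = max_{j<=i} 1 − (1 − p_(j))^(m−j+1)`).

## The synthetic cohort generator

The generator is calibrated once to the study conditions and is not a
tuning dial. Telemetry channels fluctuate around phase-specific baseline
means with AR(1) noise whose stationary SD equals the phase baseline SD
(so a simulated healthy cohort reproduces the configured diurnal
statistics) and whose per-minute autocorrelation (default 0.98) induces
realistic within-animal correlation over the 8-h averaging windows. Blood
analytes get independent Gaussian draw noise. Injured animals superpose a
normalized gamma-kernel impulse `g(t) = (t/τ)^k exp(k(1 − t/τ))` on each
responding channel — `g` starts at 0, peaks at exactly `g(τ) = 1`, and
relaxes back to baseline at a rate set by `k`; biphasic channels (WBC,
glucose) sum two kernels of opposite sign. Default kinetics anchor the
published injured-group extrema: tachycardia of 201 bpm at 8 h with slow
recovery, a WBC nadir of 3.9 × 10³/µL at 8 h recovering by ~40 h, a
platelet nadir of 132 × 10³/µL at 32 h, creatinine peaking at 2.0 mg/dL at
24 h, a delayed bilirubin peak of 0.53 mg/dL, acute hyperlactatemia of
6.3 mM, hyperglycemia of 174 mg/dL followed by hypoglycemia, a mild P/F
depression that stays above 400 on average, and cytokine impulses peaking
at 8 h (TNF-α at 16 h). Baselines that no published table constrains
(platelets 350 ± 60, creatinine 1.0 ± 0.2, glucose 100 ± 15, cytokines)
are set once to values typical of healthy pigs of this size.

SNORT is simulated as a bounded integer walk: an integer-rounded
mean-reverting process around a smooth depression/recovery path (from 11
down to ~5.5 near 12 h, recovering to ~7.6 by 72 h, giving a post-injury
median near the published 6.6), clipped to [2, 11]. Healthy animals use a
smaller observer noise so they sit at 10–11 throughout, matching the
control group's constant median of 11; mean reversion (rather than a free
random walk) keeps the within-animal variance bounded over the 10-step
grid. Mortality is Bernoulli per injured animal at 0.25; death times are
log-normal (median 18 h, σ = 0.4) truncated to (0, 40 h), reflecting that
both observed deaths preceded the 40-h timepoint, and a cohort of 8 with
two deaths near 18 h reproduces the published mean survival of 58.5 h.
All records are truncated at death; values are clipped at physical floors
with the clipping logged per animal.

What the generator does **not** emulate: between-animal random effects
(all animals share one baseline), surgery/anesthesia transients at time 0
(the published control group shows post-surgical SOFA/NEWS2 elevation at
the first timepoint; synthetic controls do not), circadian waveform shape
beyond a two-level day/night square wave, and any mechanistic
(ODE) sepsis physiology — trajectories are phenomenological. Passing
tests therefore demonstrate correctness of the derivation/scoring
machinery under the study's statistical structure, not fidelity to any
individual animal's dynamics.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero everywhere a display precision is
  applied; band lookups operate on the rounded edges, mirroring how the
  printed tables are used at the pen side.
* With `SD = 0` (constant baseline), SIRS bounds collapse onto the mean
  and every NEWS2 band edge equals the mean; downstream scoring still
  works (any deviation is then beyond ±2 SD).
* `exact_mann_whitney()` compares rank-sum deviations with a 1e-9
  tolerance so floating-point midranks cannot drop boundary assignments.
* The MAD outlier flag uses a strict inequality; when MAD is 0 it warns
  and flags exactly the values that differ from the median (constant data
  flags nothing). It only annotates — no observation is ever removed.
* Empty 8-h telemetry windows yield `NA`, which propagates as explicit
  missingness into the scorers rather than being imputed.

## Problem sizes used by the test-suite simulations

The replicated checks run at reduced but statistically adequate sizes
chosen once: threshold parameter recovery uses 100 replicate 4-animal
baseline cohorts at 60-min telemetry; the qualitative prevalence pattern
uses 100 replicate 12-animal cohorts at 30-min telemetry; mortality
calibration uses 10,000 replicate survival draws of 8 animals; classifier
accuracy uses 40 replicate 6-animal cohorts. These sizes bound the
Monte-Carlo error well below the margins being asserted.

## Known limitations

* The NEWS2 gap convention (0 points between the 0-band and ±2 SD) is a
  documented interpretation of a table whose printed cells are sparse;
  any alternative convention would shift scores for values in those gaps
  only.
* The SNORT sub-item rubric wording varies between facilities; the
  default rubric fixes item ranges summing to [2, 11] and includes the
  response-to-offered-food-and-treat item, but facility-specific rubrics
  should be passed to `snort_score()` explicitly.
* Prevalence denominators equal animals alive at each timepoint; the
  published per-timepoint percentages imply, but do not print, those
  denominators, so exact correspondence with the published table cannot
  be checked without the raw data.
* No survival modeling beyond the two printed summaries (rate and mean
  survival time) is attempted, and cytokine group statistics are used
  only to calibrate the generator.
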