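---
title: "Detecting task-evoked physiological responses in simulated EVA field data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting task-evoked physiological responses in simulated EVA field data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evaphys)
```

## The problem

Crewmembers performing field-science work during simulated planetary EVA wear
a chest strap that records heart rate (HR, beats/min), respiration rate (RR,
breaths/min) and heart rate variability (HRV, ms) at 1 Hz, together with a
device-reported HR-confidence value (0–100%). An observer logs, at roughly
minute resolution, when each crewmember switches between six activities:
baseline rest (`Base`), traversing (`ET`), observation (`EO`), handheld
instrument use (`EI`), breaking rocks (`BR`) and bagging/sterilizing samples
(`BS`). The scientific question is whether different tasks evoke reliably
different physiological responses within an individual, and this package
implements the full inferential pipeline for answering it.

Three properties of such field data dictate the design:

* **Serial dependence.** Seconds within a task episode are strongly
  autocorrelated, so raw 1 Hz samples cannot be treated as independent
  observations. The analysis unit is therefore the *occurrence mean*: one
  mean per parameter per contiguous episode of one task.
* **Non-normality and unbalance.** Occurrence-mean distributions are not
  reliably normal, and per-task occurrence counts are wildly unbalanced (a
  frequent task may contribute over a hundred means, a rare one as few as
  three). Inference is therefore a non-parametric bootstrap, not a
  parametric ANOVA, and no p-values are produced.
* **Individual heterogeneity.** Resting levels and task responses differ so
  much between people that data are never pooled across participants. Data
  *are* pooled across field deployments for one participant, but only when
  two-sample Kolmogorov–Smirnov tests cannot distinguish the deployments'
  occurrence-mean distributions.

## The pipeline

### Quality gate and task annotation

Every record carries the device's HR-confidence value, a rating of the whole
sensing system; records with confidence strictly below 50% are dropped in
their entirety (HR, RR and HRV alike), and the boundary value 50 is kept.
Each surviving second is labelled with the task whose half-open
`[start, end)` interval contains it; the boundary second belongs to the
later task, a convention fixed here because minute-scale logging cannot
adjudicate boundaries. Seconds covered by no logged task (preparation,
driving) are discarded. An optional per-file `clock_offset_s` manifest field
re-aligns an observer log whose clock ran ahead of or behind the device's.

### Occurrence means

`segment_occurrences()` groups consecutive seconds sharing a task label into
occurrences. Gaps created purely by confidence-filtered seconds do **not**
split an occurrence — the episode is defined by the task, not by data
continuity, and splitting on dropouts would inflate the effective sample
size and re-introduce the dependence the aggregation is meant to remove. A
change of label always splits. HRV needs a minimum run of valid readings for
a within-task estimate, so HRV occurrence means with fewer than
`hrv_min_samples` (default 60 s, i.e. one minute at 1 Hz; the device
requirement is not published, so this is configurable) valid seconds are
suppressed; HR/RR means are kept down to a single second. This is why HRV
analyses run on fewer data points than HR/RR analyses.

### Case assembly

For a participant observed in several deployments, the occurrence means of
each deployment (all tasks pooled, baseline included) are compared pairwise
with two-sample KS tests: a single comparison for two deployments at
α = 0.05, three comparisons for three deployments at α = 0.017 (≈ 0.05/3, a
Bonferroni-style control of the family rate). Deployments that are *not*
significantly different may be pooled into one *case*; cases are maximal
cliques of the non-significance graph, assigned greedily by descending
combined sample size with a deterministic tie-break in deployment order
(`ID < HI1 < HI2`). KS outcomes can in principle be non-transitive
(A ~ B, B ~ C, A ≁ C); the greedy maximal-clique rule resolves this
deterministically. Decisions are made separately per parameter, so one
participant's RR data may combine while their HR data do not. The default
p-value is the asymptotic Kolmogorov distribution with the standard
effective-sample-size correction (`sqrt(ne) + 0.12 + 0.11/sqrt(ne)`); an
exact small-sample method is available via `method = "exact"`.

### Bootstrap one-way ANOVA with conservative percentile intervals

Within a case there is a single participant, so the repeated-measures factor
is degenerate and the model reduces to a one-way layout over task levels on
the occurrence means. Each bootstrap replicate resamples the occurrence
means with replacement *within* each task stratum, so every replicate has
exactly the original number of data points per task and in total — the
stratified scheme respects the unbalanced design. (A pooled-resampling
variant is available behind `resampling_scheme = "pooled"` for sensitivity
analysis; it is never the default.) For every replicate all pairwise
differences of task-level means (least-square differences, LSDs; the
second-named task's mean subtracted from the first's) are recomputed, and
each task pair gets the equal-tailed percentile interval of its replicate
distribution. A difference is significant exactly when zero falls outside
its interval.

The default interval is a conservative 99.98% (per-comparison
α = 0.0002), chosen so that the family error over a full summary table of
405 comparisons stays modest: `1 − (1 − 0.0002)^405 = 7.78%`
(`family_error()`). The default replicate count is 100,000 so that each
0.01% tail rests on at least 10 order statistics; `bootstrap_spec()` warns
when the expected per-tail replicate count drops below 10. Equal-tailed
percentile intervals (not BCa) are used because they are the simplest
interval consistent with the procedure's description; quantiles use R's
default type-7 interpolation. With identical data in all strata the
replicate distribution is degenerate, every interval is `[0, 0]`, and
nothing is significant — the zero-in-interval rule handles the edge case
without special-casing.

All 15 pairs among the six task levels are always emitted per case; pairs
involving a task the participant never performed are reported as "not
performed" (missing estimate), and such pairs are excluded from summary
denominators. `summarize_significance()` then counts significant cases per
contrast and parameter with nearest-integer percentages; exact counts are
always reported alongside, since rounded percentages alone cannot be
validated.

## The synthetic-data generator

No field data ship with the package; `generate_campaign()` produces streams,
task logs and a manifest with the statistical structure the analysis
assumes, and returns the ground truth needed for recovery tests. The default
configuration mirrors the motivating campaign's shape: 8 participants — two
in all three deployments (`ID`, `HI1`, `HI2`), two in two, four in one — with
2 EVAs per participant-deployment pair, i.e. 28 stream files.

Per second, each parameter is `baseline + task effect + carry-over + AR(1)
noise`:

* **Baselines** are individual-specific, drawn once per participant from
  realistic resting distributions (HR ≈ N(72, 6) bpm, RR ≈ N(14, 1.5)
  breaths/min, HRV ≈ N(70, 8) ms) deterministically from the seed.
* **Task effects** are additive shifts encoding strenuous > stationary
  (HR: BR +28, ET +25, EO +18, BS +15, EI +12 bpm over baseline; RR scaled
  similarly) with *negative* HRV shifts under load, so baseline rest has the
  lowest HR/RR and the highest HRV.
* **Carry-over**: after leaving a strenuous task (`ET`, `BR`) its effect
  decays exponentially with a configurable half-life (default 60 s) into
  the following tasks — mimicking the way observation pauses right after a
  traverse inherit elevated readings. Calibration and recovery tests disable
  it (`carryover_halflife_s = 0`) because it biases short follow-on tasks by
  design.
* **Noise** is stationary AR(1) (default ρ = 0.8 at 1 Hz, marginal SDs 3
  bpm / 1.5 brpm / 5 ms). AR(1) is the minimal serial-dependence model — the
  motivating analysis only requires that raw seconds be dependent — and an
  optional standardized-lognormal innovation switch provides a skewed
  alternative rather than asserting any distributional form.
* **Imperfections**: HR-confidence values fall below 50 with a configurable
  per-second probability (default 0.05); HRV is missing for the first
  `hrv_warmup_s` seconds of each stream (default 120 s), which is what makes
  HRV occurrence counts fall below HR/RR counts; and the written task log
  perturbs transition times by U(−j, +j) and then rounds them to whole
  minutes, emulating minute-scale manual timestamping. With `j = 0` the log
  is exact; the documented mislabelling bound (at most `2j` seconds per
  transition) holds for `j ≥ 30` s because rounding itself can move a
  transition up to 30 s. Default `j = 30`.
* **Schedules**: the `"auto"` template opens with a deployment-appropriate
  baseline segment (30 min for `ID`, 10 min for the `HI` deployments,
  matching the two baseline-collection protocols), then alternates traverse
  and observation blocks before instrument/rock-breaking/bagging site work.
  Durations are randomized within realistic ranges (2–7 min per episode).

What the generator does **not** emulate: biomechanically realistic waveform
synthesis, motion artefacts beyond the confidence gate, circadian or
fatigue drift across a day, and any correlation between the three parameters
beyond their shared task structure. Passing tests therefore demonstrate that
the pipeline recovers the structure it models — additive task shifts under
serial noise, dropout and label jitter — not that the model captures every
feature of real field physiology.

Identical configuration and seed give byte-identical output files; every
EVA's randomness derives deterministically from (seed, participant,
deployment, EVA index), so single EVAs can be regenerated independently.

## Numerical and design choices

* Half-open `[start, end)` intervals, boundary second to the later task.
* The confidence gate removes whole records, never single parameters.
* Stream values are written at 0.1 resolution; quantities are reported in
  the device's units throughout (bpm, breaths/min, ms).
* Bootstrap seeds: each case × parameter derives its own RNG stream from the
  spec seed, so adding or removing one case never changes another's result.
* Percentages in summaries are rounded to the nearest integer, with exact
  `k/n` kept beside them.
* Degenerate inputs: occurrences with zero valid values for a parameter are
  suppressed with a message; cases with fewer than two task levels are
  skipped with a message; single-occurrence strata are legal and resample to
  themselves.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config(seed = 1)
res <- run_pipeline(cfg, "campaign-out", n_replicates = 1e5)

res$cases                      # which deployments pooled, per participant/parameter
dplyr::filter(res$pairs, parameter == "HR", case_id == 1)
dplyr::filter(res$summary, contrast == "Total")
```

The vignette keeps this chunk unevaluated to stay light; the README shows a
small run with its actual printed output. Test-suite problem sizes are
deliberately modest (synthetic campaigns of 2 participants, bootstrap
calibration at 2,000 replicates × 2,000 null cases) — the package's own
choice of desk-scale defaults; all thresholds in the tests derive from the
binomial Monte-Carlo error of those sizes.

## Known limitations

* The exact resampling unit and replicate count of the original SAS
  procedure are not published; the stratified scheme documented above is
  this package's explicit default, flagged as an interpretation rather than
  a reconstruction.
* Percentile intervals at small per-task `n` are slightly anti-conservative
  (the bootstrap variance of a stratum mean underestimates the sampling
  variance by a factor `(n-1)/n`); the calibration tests quantify this at
  the sizes they run.
* Published LSD tables from the motivating study are not reproducible from
  the package because the underlying field data were never deposited; the
  package instead verifies the study's printed arithmetic and validates the
  method on synthetic data with known truth.
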