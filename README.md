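# evaphys

Task-evoked physiological response analysis for simulated planetary EVA
field campaigns.

## The problem

During simulated extravehicular activity (EVA), field crewmembers wear a
chest strap recording heart rate (HR, beats/min), respiration rate (RR,
breaths/min) and heart rate variability (HRV, ms) at 1 Hz, plus a
device-reported HR-confidence value. An observer logs, at minute resolution,
transitions between six activities: baseline rest (`Base`), traversing
(`ET`), observation (`EO`), instrument use (`EI`), breaking rocks (`BR`) and
bagging/sterilizing samples (`BS`). The question: does a given task evoke a
reliably different physiological response *within an individual*?

Raw 1 Hz samples are serially dependent, occurrence counts per task are
wildly unbalanced, and the distributions are not reliably normal — so the
pipeline is built around three ideas:

1. **Occurrence means.** Each contiguous episode of one task is collapsed to
   one mean per parameter; all inference runs on these means. Records with
   HR-confidence below 50% are removed first (the boundary value 50 is
   kept), and seconds outside any logged task are discarded.
2. **KS case pooling.** For a participant observed in several deployments,
   per-deployment occurrence-mean distributions are compared with two-sample
   Kolmogorov–Smirnov tests (α = 0.05 for one comparison, α = 0.017 ≈ 0.05/3
   for three). Indistinguishable deployments pool into one *case*; inference
   is always per case, never across participants.
3. **Stratified bootstrap one-way ANOVA.** Within each case, occurrence
   means are resampled with replacement within each task stratum (replicates
   keep the original per-task counts). For each task pair the least-square
   difference `LSD(a, b) = mean(a) − mean(b)` gets an equal-tailed
   percentile confidence interval at a conservative 99.98%; the pair is
   significant exactly when zero lies outside. No p-values are produced.
   Over a full 405-comparison summary the family-wise error is
   `1 − (1 − 0.0002)^405 = 7.78%`.

A synthetic-data generator (`generate_campaign()`) emulates the campaign
structure — 8 participants over deployments `ID`/`HI1`/`HI2`, 28 EVAs,
individual baselines, task-specific shifts, AR(1) noise, carry-over after
strenuous tasks, confidence dropouts, HRV warm-up gaps, minute-rounded task
logs — so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(evaphys)

cfg <- scenario_config(
  n_participants = 2,
  deployments_per_participant = list(c("ID", "HI1"), "HI1"),
  evas_per_deployment = 2,
  seed = 7
)
res <- run_pipeline(cfg, tempfile(), n_replicates = 1e5, ci_level = 99.98)

res$cases
#> # A tibble: 6 × 5
#>   case_id participant parameter deployments n_means
#>     <int> <chr>       <chr>     <chr>         <int>
#> 1       1 P01         HR        ID/HI1           48
#> 2       2 P02         HR        HI1              21
#> 3       1 P01         HRV       ID/HI1           48
#> 4       2 P02         HRV       HI1              21
#> 5       1 P01         RR        ID/HI1           48
#> 6       2 P02         RR        HI1              21

dplyr::filter(res$pairs, parameter == "HR", case_id == 1, task_a == "Base")
#> # A tibble: 5 × 11
#>   case_id parameter contrast task_a task_b   lsd ci_low ci_high significant   n_a   n_b
#>     <int> <chr>     <chr>    <chr>  <chr>  <dbl>  <dbl>   <dbl> <lgl>       <int> <int>
#> 1       1 HR        Base-BR  Base   BR     -27.2  -30.0   -24.8 TRUE            4     6
#> 2       1 HR        Base-BS  Base   BS     -27.4  -29.3   -26.1 TRUE            4     6
#> 3       1 HR        Base-EI  Base   EI     -14.4  -17.0   -12.4 TRUE            4     6
#> 4       1 HR        Base-EO  Base   EO     -28.0  -31.2   -25.7 TRUE            4    11
#> 5       1 HR        Base-ET  Base   ET     -26.0  -26.7   -25.3 TRUE            4    15
```

(Your numbers will match with the same seed; the LSD signs read
"second-named task's mean subtracted from the first's", so negative
`Base-X` HR values say every field task raised heart rate above baseline.)
`res$summary` is the per-contrast significance-count table with
nearest-integer percentages, and `res$mean_responses` holds the per-case
per-task grand means behind the usual bar-chart figures
(`plot_mean_response()` renders them).

The published per-contrast significance counts of the motivating field
study ship as reference data (`reported_significance_counts()`,
`reported_parameter_totals()`); their help page documents two internal
inconsistencies of the source table that the package reports rather than
emulates.

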