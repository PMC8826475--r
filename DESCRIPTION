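Package: evaphys
Title: Task-Evoked Physiological Response Analysis for Simulated Planetary EVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 1 Hz wearable physiological streams (heart
    rate, respiration rate, heart rate variability) recorded while crewmembers
    perform field-science tasks during simulated extravehicular activity
    (EVA). The package quality-filters streams with a device heart-rate
    confidence gate, annotates every second with the task being performed,
    collapses each contiguous task occurrence to one mean (the analysis unit,
    which weakens serial dependence), decides per participant and parameter
    which field deployments may be pooled into a single case via two-sample
    Kolmogorov-Smirnov tests with multiplicity-adjusted alpha levels, and
    detects pairwise task differences with a non-parametric stratified
    bootstrap one-way ANOVA that reports conservative percentile confidence
    intervals for every least-square difference. A synthetic-data generator
    emulates the measurement structure of a multi-deployment field campaign
    (individual baselines, task-specific shifts, AR(1) serial noise,
    carry-over after strenuous tasks, minute-scale task-log jitter,
    confidence dropouts, HRV warm-up gaps) so the full pipeline is testable
    end to end without any field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    yaml
Config/testthat/edition: 3
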