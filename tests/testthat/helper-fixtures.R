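# shared fixtures, built in code

# minimal noise-free scenario with a fixed schedule; effects chosen so task
# ordering is unambiguous
quiet_config <- function(schedule, seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_participants = 1,
    deployments_per_participant = list("ID"),
    evas_per_deployment = 1,
    task_schedule_template = schedule,
    baseline_mu = matrix(c(70, 14, 70), 1, dimnames = list("P01", c("HR", "RR", "HRV"))),
    noise_sd = c(HR = 0, RR = 0, HRV = 0),
    ar1_rho = 0,
    dropout_rate = 0,
    hrv_warmup_s = 0,
    label_jitter_s = 0,
    carryover_halflife_s = 0,
    seed = seed
  )
  do.call(scenario_config, utils::modifyList(defaults, args))
}

# a small two-participant campaign exercising multi-deployment structure;
# built at most once per test run
small_campaign <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- scenario_config(
      n_participants = 2,
      deployments_per_participant = list(c("ID", "HI1"), c("ID", "HI1", "HI2")),
      evas_per_deployment = 2,
      seed = 42
    )
    dir <- file.path(tempdir(), "evaphys-small-campaign")
    unlink(dir, recursive = TRUE)
    campaign <- generate_campaign(cfg, dir)
    labeled <- ingest_campaign(file.path(dir, "manifest.csv"))
    means <- suppressMessages(occurrence_means(segment_occurrences(labeled)))
    cache <<- list(config = cfg, campaign = campaign, labeled = labeled,
                   means = means, dir = dir)
    cache
  }
})

# labelled-record fixture: one row per second with chosen labels/confidences
make_labeled <- function(task_code,
                         hr = seq(80, length.out = length(task_code)),
                         conf = rep(100, length(task_code)),
                         interval_id = NULL) {
  out <- tibble::tibble(
    time_s = seq_along(task_code) - 1,
    hr_bpm = hr,
    rr_brpm = hr / 5,
    hrv_ms = hr - 10,
    hr_confidence = conf,
    task_code = task_code
  )
  if (!is.null(interval_id)) out$interval_id <- interval_id
  out
}

# occurrence-mean fixture for the inference modules
make_means <- function(values_by_task, participant = "P01", deployment = "ID",
                       parameter = "HR") {
  tibble::tibble(
    participant = participant,
    deployment = deployment,
    eva = 1L,
    task_code = rep(names(values_by_task), lengths(values_by_task)),
    occurrence_index = unlist(lapply(lengths(values_by_task), seq_len)),
    parameter = parameter,
    mean_value = unlist(values_by_task, use.names = FALSE),
    n_samples = 60L
  )
}

write_stream_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
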