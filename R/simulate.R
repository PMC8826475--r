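#' Simulate one EVA's physiological stream and task logs
#'
#' Generates a 1 Hz stream of heart rate, respiration rate and HRV for a
#' single participant-deployment-EVA triple, together with the true task
#' intervals and the jittered, minute-rounded task log an observer would have
#' recorded. Each second's expected value is
#' `baseline + task effect + carry-over`, where the carry-over term decays
#' exponentially (half-life `carryover_halflife_s`) after leaving a strenuous
#' task (`ET` or `BR`), plus stationary AR(1) noise. HRV is missing for the
#' first `hrv_warmup_s` seconds; a `dropout_rate` fraction of seconds (in
#' expectation) carries an HR-confidence value below 50, the rest at or above
#' 50.
#'
#' @param config An [scenario_config()] object.
#' @param participant Participant id (`"P01"`) or 1-based index.
#' @param deployment Deployment code, one of `"ID"`, `"HI1"`, `"HI2"`.
#' @param eva_index 1-based EVA index within the deployment.
#'
#' @return A list with elements `stream` (tibble: `time_s`, `hr_bpm`,
#'   `rr_brpm`, `hrv_ms`, `hr_confidence`), `true_log` and `jittered_log`
#'   (tibbles of half-open task intervals: `start_s`, `end_s`, `task_code`,
#'   `participant`, `deployment`).
#' @examples
#' cfg <- scenario_config(seed = 7)
#' eva <- generate_eva(cfg, "P01", "ID", 1)
#' head(eva$stream)
#' @export
generate_eva <- function(config, participant, deployment, eva_index = 1) {
  stopifnot(inherits(config, "eva_scenario"))
  p_idx <- resolve_participant(config, participant)
  p_id <- participant_ids(config$n_participants)[p_idx]
  if (!deployment %in% eva_deployment_codes()) {
    stopf("configuration error: unknown deployment code: %s", deployment)
  }
  if (eva_index < 1 || eva_index > config$evas_per_deployment) {
    stopf("eva_index %s out of range 1..%d", format(eva_index), config$evas_per_deployment)
  }
  d_idx <- match(deployment, eva_deployment_codes())

  restore <- local_rng(derive_seed(config$seed, p_idx, d_idx, as.integer(eva_index)))
  on.exit(restore())

  sched <- eva_schedule(config, deployment)
  total_s <- sum(sched$duration_s)
  starts <- cumsum(c(0, sched$duration_s[-nrow(sched)]))
  true_log <- tibble::tibble(
    start_s = starts,
    end_s = starts + sched$duration_s,
    task_code = sched$task_code,
    participant = p_id,
    deployment = deployment
  )

  time_s <- seq_len(total_s) - 1L
  task_per_s <- rep(sched$task_code, sched$duration_s)
  carry_w <- carryover_weights(true_log, total_s, config$carryover_halflife_s)

  values <- lapply(eva_parameters(), function(par) {
    mu <- config$baseline_mu[p_idx, par] +
      config$task_effect[task_per_s, par] +
      carry_w$weight * config$task_effect[carry_w$source_task, par] *
        (carry_w$source_task != "Base")
    noise <- ar1_noise(total_s, config$ar1_rho, config$noise_sd[[par]], config$noise_dist)
    pmax(round(as.numeric(mu) + noise, 1), 1)
  })
  names(values) <- eva_parameters()

  hrv <- values$HRV
  if (config$hrv_warmup_s > 0) {
    hrv[seq_len(min(config$hrv_warmup_s, total_s))] <- NA_real_
  }
  low <- stats::runif(total_s) < config$dropout_rate
  conf <- integer(total_s)
  conf[low] <- sample(0:49, sum(low), replace = TRUE)
  conf[!low] <- sample(50:100, sum(!low), replace = TRUE)

  stream <- tibble::tibble(
    time_s = time_s,
    hr_bpm = values$HR,
    rr_brpm = values$RR,
    hrv_ms = hrv,
    hr_confidence = conf
  )

  jittered_log <- jitter_log(true_log, config$label_jitter_s)
  list(stream = stream, true_log = true_log, jittered_log = jittered_log)
}

resolve_participant <- function(config, participant) {
  ids <- participant_ids(config$n_participants)
  if (is.numeric(participant)) {
    p_idx <- as.integer(participant)
  } else {
    p_idx <- match(participant, ids)
  }
  if (is.na(p_idx) || p_idx < 1 || p_idx > config$n_participants) {
    stopf("unknown participant: %s", format(participant))
  }
  p_idx
}

# deployment-appropriate schedule; draws from the current RNG state
eva_schedule <- function(config, deployment) {
  if (!identical(config$task_schedule_template, "auto")) {
    sched <- config$task_schedule_template
    return(tibble::tibble(
      task_code = as.character(sched$task_code),
      duration_s = as.integer(sched$duration_s)
    ))
  }
  base_dur <- if (deployment == "ID") 1800L else 600L
  rows <- list(c("Base", base_dur))
  for (i in seq_len(sample(2:3, 1))) {
    rows <- c(rows, list(
      c("ET", sample(240:420, 1)),
      c("EO", sample(120:240, 1))
    ))
  }
  for (i in seq_len(sample(1:2, 1))) {
    rows <- c(rows, list(
      c("EI", sample(180:300, 1)),
      c("BR", sample(120:240, 1)),
      c("BS", sample(120:240, 1))
    ))
  }
  rows <- c(rows, list(c("ET", sample(240:360, 1))))
  tibble::tibble(
    task_code = vapply(rows, `[`, "", 1),
    duration_s = as.integer(vapply(rows, `[`, "", 2))
  )
}

# stationary AR(1) noise with unit-time spacing; innovations standardised so
# the marginal SD equals sd regardless of rho or innovation shape
ar1_noise <- function(n, rho, sd, dist = "gaussian") {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- if (dist == "lognormal") {
    raw <- stats::rlnorm(n, 0, 1)
    (raw - exp(0.5)) / sqrt((exp(1) - 1) * exp(1)) * innov_sd
  } else {
    stats::rnorm(n, 0, innov_sd)
  }
  if (rho == 0) return(e)
  x0 <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, rho, method = "recursive", init = x0))
}

# per-second decay weight and source task of the most recent strenuous
# occurrence that has already ended; weight 0 before any strenuous task
carryover_weights <- function(true_log, total_s, halflife_s) {
  weight <- numeric(total_s)
  source_task <- rep("Base", total_s)
  if (halflife_s <= 0) return(list(weight = weight, source_task = source_task))
  stren <- true_log[true_log$task_code %in% c("ET", "BR"), ]
  if (nrow(stren) == 0) return(list(weight = weight, source_task = source_task))
  for (i in seq_len(nrow(stren))) {
    from <- stren$end_s[i]
    to <- if (i < nrow(stren)) stren$end_s[i + 1] else total_s
    if (from >= to) next
    idx <- (from + 1):to   # seconds from..to-1, 1-based
    t_since <- (from:(to - 1)) - from + 1
    weight[idx] <- 2^(-t_since / halflife_s)
    source_task[idx] <- stren$task_code[i]
  }
  list(weight = weight, source_task = source_task)
}

# observer log: interior transitions shifted U(-j, +j), rounded to whole
# minutes, kept strictly increasing on the minute grid; exact when j = 0
jitter_log <- function(true_log, label_jitter_s) {
  if (label_jitter_s == 0 || nrow(true_log) < 2) return(true_log)
  starts <- true_log$start_s
  n <- length(starts)
  jit <- starts[-1] + stats::runif(n - 1, -label_jitter_s, label_jitter_s)
  jit <- round(jit / 60) * 60
  for (i in seq_along(jit)) {
    prev <- if (i == 1) starts[1] else jit[i - 1]
    if (jit[i] <= prev) jit[i] <- prev + 60
  }
  out <- true_log
  out$start_s <- c(starts[1], jit)
  out$end_s <- c(jit, true_log$end_s[n])
  out[out$start_s < out$end_s, ]
}

#' Generate a full synthetic campaign on disk
#'
#' Writes one stream CSV and one task-log CSV per (participant, deployment,
#' EVA) plus a manifest enumerating them, and returns the ground truth needed
#' for parameter-recovery tests. The default configuration reproduces the
#' study shape: 8 participants, deployments drawn from `{ID, HI1, HI2}`, and
#' 28 EVAs in total.
#'
#' @param config An [scenario_config()] object.
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, a list with `manifest` (tibble), `truth` (list with
#'   `levels`: true per participant-deployment-parameter-task mean levels, and
#'   `occurrences`: true task intervals per EVA), and `dir`.
#' @seealso [read_manifest()], [ingest_campaign()]
#' @export
generate_campaign <- function(config, out_dir) {
  stopifnot(inherits(config, "eva_scenario"))
  dir.create(file.path(out_dir, "streams"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "logs"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stopf("I/O error: cannot write to output directory: %s", out_dir)
  }

  ids <- participant_ids(config$n_participants)
  manifest <- list()
  occurrences <- list()
  k <- 0L
  for (p_idx in seq_len(config$n_participants)) {
    for (dep in config$deployments_per_participant[[p_idx]]) {
      for (e in seq_len(config$evas_per_deployment)) {
        k <- k + 1L
        eva <- generate_eva(config, p_idx, dep, e)
        stem <- sprintf("%s_%s_e%d", ids[p_idx], dep, e)
        stream_file <- file.path("streams", paste0(stem, "_stream.csv"))
        log_file <- file.path("logs", paste0(stem, "_log.csv"))
        readr::write_csv(eva$stream, file.path(out_dir, stream_file), na = "")
        write_task_log(eva$jittered_log, file.path(out_dir, log_file))
        manifest[[k]] <- tibble::tibble(
          participant = ids[p_idx], deployment = dep, eva = e,
          stream_file = stream_file, log_file = log_file,
          clock_offset_s = 0
        )
        occurrences[[k]] <- dplyr::mutate(eva$true_log, eva = e, .after = "deployment")
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  occurrences <- dplyr::bind_rows(occurrences)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  levels <- true_levels(config)
  readr::write_csv(levels, file.path(out_dir, "truth_levels.csv"))
  readr::write_csv(occurrences, file.path(out_dir, "truth_occurrences.csv"))

  invisible(list(
    manifest = manifest,
    truth = list(levels = levels, occurrences = occurrences),
    dir = out_dir
  ))
}

# true mean level (baseline + task effect, carry-over excluded) per
# participant-deployment-parameter-task
true_levels <- function(config) {
  ids <- participant_ids(config$n_participants)
  grid <- tidyr::expand_grid(
    p_idx = seq_len(config$n_participants),
    parameter = eva_parameters(),
    task_code = eva_task_codes()
  )
  grid$participant <- ids[grid$p_idx]
  grid$true_level <- config$baseline_mu[cbind(
    grid$p_idx, match(grid$parameter, colnames(config$baseline_mu)))] +
    config$task_effect[cbind(grid$task_code, grid$parameter)]
  deps <- tibble::tibble(
    participant = rep(ids, lengths(config$deployments_per_participant)),
    deployment = unlist(config$deployments_per_participant)
  )
  out <- dplyr::inner_join(deps, grid[, c("participant", "parameter", "task_code", "true_level")],
                           by = "participant", relationship = "many-to-many")
  dplyr::arrange(out, .data$participant, .data$deployment, .data$parameter, .data$task_code)
}

# task-log CSV dialect: transition rows only
write_task_log <- function(log, path) {
  readr::write_csv(
    tibble::tibble(
      time_s = log$start_s,
      participant = log$participant,
      task_code = log$task_code,
      note = ""
    ),
    path
  )
}
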