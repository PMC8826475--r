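#' Scenario configuration for the synthetic campaign generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_eva()] and [generate_campaign()]. The defaults reproduce the
#' measurement structure of the motivating field campaign: 8 participants
#' rotating across up to three deployments (`ID`, `HI1`, `HI2`), 28 simulated
#' EVAs in total, individual-specific resting levels, task-specific additive
#' shifts (strenuous traversing/rock-breaking larger than stationary
#' instrument/bagging work; baseline lowest for HR/RR and highest for HRV),
#' AR(1) serial noise, exponential carry-over after strenuous tasks,
#' minute-scale task-log jitter, HR-confidence dropouts, and an HRV warm-up
#' gap at the start of each stream.
#'
#' @param n_participants Number of participants (default 8).
#' @param deployments_per_participant List (length `n_participants`) of
#'   deployment code vectors, each a subset of `c("ID","HI1","HI2")`. The
#'   default assigns two participants to all three deployments, two to two,
#'   and four to one, giving 14 participant-deployment pairs.
#' @param evas_per_deployment EVAs per participant-deployment pair (default 2,
#'   so the default campaign has 28 stream files).
#' @param task_schedule_template Either the string `"auto"` (a randomized
#'   traverse/observe opening followed by instrument/rock/bagging site blocks,
#'   preceded by a deployment-appropriate baseline segment) or a data frame
#'   with columns `task_code`, `duration_s` used verbatim for every EVA.
#' @param baseline_mu Per-participant resting levels: a numeric matrix with
#'   `n_participants` rows and columns `HR`, `RR`, `HRV` (bpm, breaths/min,
#'   ms). `NULL` (default) draws participant levels once, deterministically
#'   from `seed`, around 72 bpm / 14 brpm / 70 ms.
#' @param task_effect Additive task shifts: numeric matrix with rows `Base`,
#'   `BR`, `BS`, `EI`, `EO`, `ET` and columns `HR`, `RR`, `HRV`, in parameter
#'   units. The default encodes strenuous > stationary ordering and negative
#'   HRV shifts under load.
#' @param carryover_halflife_s Half-life (s) of the exponential residual added
#'   after leaving a strenuous task (`ET`, `BR`); 0 disables carry-over.
#' @param ar1_rho Lag-1 autocorrelation of the per-second noise, in `[0, 1)`.
#' @param noise_sd Stationary noise standard deviation per parameter, a named
#'   numeric vector `c(HR=, RR=, HRV=)`.
#' @param dropout_rate Per-second probability that the HR-confidence value
#'   falls below the 50% quality gate, in `[0, 1]`.
#' @param hrv_warmup_s Seconds of missing HRV at the start of every stream.
#' @param label_jitter_s Maximum absolute shift (s) applied to logged task
#'   transition times before rounding them to whole minutes; 0 gives an exact
#'   log. Values of at least 30 s keep the documented mislabelling bound.
#' @param noise_dist `"gaussian"` (default) or `"lognormal"` innovation shape
#'   for the AR(1) noise (standardised to mean 0 and the stated SD).
#' @param seed Integer seed controlling every random element; identical
#'   configurations with identical seeds generate byte-identical files.
#'
#' @return An object of class `eva_scenario` (a validated list).
#' @examples
#' cfg <- scenario_config(seed = 1)
#' cfg$n_participants
#' @export
scenario_config <- function(n_participants = 8,
                            deployments_per_participant = NULL,
                            evas_per_deployment = 2,
                            task_schedule_template = "auto",
                            baseline_mu = NULL,
                            task_effect = NULL,
                            carryover_halflife_s = 60,
                            ar1_rho = 0.8,
                            noise_sd = c(HR = 3, RR = 1.5, HRV = 5),
                            dropout_rate = 0.05,
                            hrv_warmup_s = 120,
                            label_jitter_s = 30,
                            noise_dist = c("gaussian", "lognormal"),
                            seed = 1L) {
  noise_dist <- match.arg(noise_dist)
  if (is.null(deployments_per_participant)) {
    deployments_per_participant <- default_deployments(n_participants)
  }
  if (is.null(task_effect)) task_effect <- default_task_effect()
  if (is.null(baseline_mu)) {
    baseline_mu <- draw_baselines(n_participants, seed)
  }

  cfg <- structure(
    list(
      n_participants = as.integer(n_participants),
      deployments_per_participant = deployments_per_participant,
      evas_per_deployment = as.integer(evas_per_deployment),
      task_schedule_template = task_schedule_template,
      baseline_mu = baseline_mu,
      task_effect = task_effect,
      carryover_halflife_s = carryover_halflife_s,
      ar1_rho = ar1_rho,
      noise_sd = noise_sd,
      dropout_rate = dropout_rate,
      hrv_warmup_s = as.integer(hrv_warmup_s),
      label_jitter_s = label_jitter_s,
      noise_dist = noise_dist,
      seed = as.integer(seed)
    ),
    class = "eva_scenario"
  )
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  if (cfg$n_participants < 1) stopf("configuration error: n_participants must be >= 1")
  if (length(cfg$deployments_per_participant) != cfg$n_participants) {
    stopf("configuration error: deployments_per_participant must have one entry per participant")
  }
  bad_dep <- setdiff(unlist(cfg$deployments_per_participant), eva_deployment_codes())
  if (length(bad_dep)) {
    stopf("configuration error: unknown deployment code(s): %s", paste(bad_dep, collapse = ", "))
  }
  if (cfg$evas_per_deployment < 1) stopf("configuration error: evas_per_deployment must be >= 1")
  if (!identical(cfg$task_schedule_template, "auto")) {
    sched <- cfg$task_schedule_template
    if (!is.data.frame(sched) || !all(c("task_code", "duration_s") %in% names(sched))) {
      stopf("configuration error: task_schedule_template must be \"auto\" or a data frame with task_code and duration_s")
    }
    if (nrow(sched) == 0) stopf("configuration error: zero-length task schedule")
    bad <- setdiff(sched$task_code, eva_task_codes())
    if (length(bad)) stopf("configuration error: unknown task code(s): %s", paste(bad, collapse = ", "))
    if (any(sched$duration_s <= 0)) stopf("configuration error: all schedule durations must be > 0")
  }
  if (!is.matrix(cfg$baseline_mu) ||
      nrow(cfg$baseline_mu) != cfg$n_participants ||
      !all(eva_parameters() %in% colnames(cfg$baseline_mu))) {
    stopf("configuration error: baseline_mu must be an n_participants x {HR,RR,HRV} matrix")
  }
  if (!is.matrix(cfg$task_effect) ||
      !all(eva_task_codes() %in% rownames(cfg$task_effect)) ||
      !all(eva_parameters() %in% colnames(cfg$task_effect))) {
    stopf("configuration error: task_effect must be a {Base,BR,BS,EI,EO,ET} x {HR,RR,HRV} matrix")
  }
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) stopf("configuration error: ar1_rho must lie in [0, 1)")
  if (!all(eva_parameters() %in% names(cfg$noise_sd)) || any(cfg$noise_sd < 0)) {
    stopf("configuration error: noise_sd must be a non-negative named vector over HR, RR, HRV")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) {
    stopf("configuration error: dropout_rate must lie in [0, 1]")
  }
  if (cfg$hrv_warmup_s < 0) stopf("configuration error: hrv_warmup_s must be >= 0")
  if (cfg$label_jitter_s < 0) stopf("configuration error: label_jitter_s must be >= 0")
  cfg
}

# two participants in all three deployments, two in two, remainder in one;
# single-deployment participants alternate HI1 / HI2
default_deployments <- function(n_participants) {
  base <- list(
    c("ID", "HI1"),
    c("ID", "HI1", "HI2"),
    c("ID", "HI1", "HI2"),
    c("ID", "HI1"),
    "HI1", "HI1", "HI2", "HI2"
  )
  if (n_participants <= 8) return(base[seq_len(n_participants)])
  extra <- lapply(seq_len(n_participants - 8), function(i) {
    if (i %% 2 == 1) "HI1" else "HI2"
  })
  c(base, extra)
}

default_task_effect <- function() {
  m <- rbind(
    Base = c(0,    0,   0),
    BR   = c(28,   7,  -18),
    BS   = c(15,   3.5, -10),
    EI   = c(12,   2.5, -8),
    EO   = c(18,   4,  -10),
    ET   = c(25,   6,  -15)
  )
  colnames(m) <- eva_parameters()
  m
}

draw_baselines <- function(n_participants, seed) {
  rng <- local_rng(derive_seed(seed, 97L))
  m <- cbind(
    HR = stats::rnorm(n_participants, 72, 6),
    RR = stats::rnorm(n_participants, 14, 1.5),
    HRV = stats::rnorm(n_participants, 70, 8)
  )
  rng()
  rownames(m) <- participant_ids(n_participants)
  round(m, 2)
}

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

# set the RNG state locally; returns a restorer to call when done
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' @export
print.eva_scenario <- function(x, ...) {
  n_pd <- sum(lengths(x$deployments_per_participant))
  cat("<eva_scenario>\n")
  cat(sprintf("  participants: %d (%d participant-deployment pairs)\n",
              x$n_participants, n_pd))
  cat(sprintf("  EVAs: %d per pair (%d total)\n",
              x$evas_per_deployment, n_pd * x$evas_per_deployment))
  cat(sprintf("  noise: %s AR(1) rho=%.2f, sd HR=%.1f RR=%.1f HRV=%.1f\n",
              x$noise_dist, x$ar1_rho,
              x$noise_sd[["HR"]], x$noise_sd[["RR"]], x$noise_sd[["HRV"]]))
  cat(sprintf("  dropout=%.2f, hrv warm-up=%ds, label jitter=%ss, carry-over t1/2=%ss, seed=%d\n",
              x$dropout_rate, x$hrv_warmup_s, format(x$label_jitter_s),
              format(x$carryover_halflife_s), x$seed))
  invisible(x)
}
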