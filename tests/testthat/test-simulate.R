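test_that("noiseless additive model reproduces baseline + task effect exactly", {
  sched <- data.frame(task_code = "ET", duration_s = 120)
  eff <- default_task_effect()
  eff["ET", "HR"] <- 20
  cfg <- quiet_config(sched, task_effect = eff)
  eva <- generate_eva(cfg, "P01", "ID", 1)
  expect_equal(nrow(eva$stream), 120)
  expect_true(all(eva$stream$hr_bpm == 90))
  expect_true(all(eva$stream$hr_confidence >= 50))
  expect_equal(eva$jittered_log, eva$true_log)
})

test_that("configuration errors name the offending task code and reject empty schedules", {
  expect_error(
    quiet_config(data.frame(task_code = "XX", duration_s = 60)),
    "XX"
  )
  expect_error(
    quiet_config(data.frame(task_code = character(), duration_s = numeric())),
    "zero-length"
  )
  expect_error(
    quiet_config(data.frame(task_code = "ET", duration_s = 0)),
    "> 0"
  )
  expect_error(scenario_config(ar1_rho = 1), "ar1_rho")
  expect_error(scenario_config(dropout_rate = 1.2), "dropout_rate")
})

test_that("stronger task effects give larger occurrence means in nearly all replicates", {
  sched <- data.frame(task_code = c("ET", "EI"), duration_s = c(300, 300))
  eff <- default_task_effect()
  eff["ET", "HR"] <- 25
  eff["EI", "HR"] <- 5
  wins <- vapply(1:1000, function(s) {
    cfg <- quiet_config(sched, task_effect = eff,
                        noise_sd = c(HR = 3, RR = 0, HRV = 0),
                        ar1_rho = 0.8, seed = s)
    hr <- generate_eva(cfg, 1, "ID", 1)$stream$hr_bpm
    mean(hr[1:300]) > mean(hr[301:600])
  }, TRUE)
  expect_gte(mean(wins), 0.99)
})

test_that("HR-confidence dropouts occur at the configured rate", {
  cfg <- quiet_config(data.frame(task_code = "EO", duration_s = 1000),
                      dropout_rate = 0.2, seed = 5)
  conf <- generate_eva(cfg, 1, "ID", 1)$stream$hr_confidence
  frac <- mean(conf < 50)
  tol <- 3 * sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(frac - 0.2), tol)
  expect_true(all(conf >= 0 & conf <= 100))
})

test_that("long occurrence means converge to baseline + effect without carry-over", {
  n <- 3600
  cfg <- quiet_config(data.frame(task_code = "BR", duration_s = n),
                      noise_sd = c(HR = 3, RR = 1.5, HRV = 5),
                      ar1_rho = 0, seed = 9)
  stream <- generate_eva(cfg, 1, "ID", 1)$stream
  expect_lt(abs(mean(stream$hr_bpm) - (70 + 28)), 3 * 3 / sqrt(n))
  expect_lt(abs(mean(stream$rr_brpm) - (14 + 7)), 3 * 1.5 / sqrt(n))
})

test_that("lognormal noise switch keeps the stated marginal SD", {
  cfg <- quiet_config(data.frame(task_code = "Base", duration_s = 20000),
                      noise_sd = c(HR = 3, RR = 0, HRV = 0),
                      ar1_rho = 0, noise_dist = "lognormal", seed = 2)
  hr <- generate_eva(cfg, 1, "ID", 1)$stream$hr_bpm
  expect_lt(abs(stats::sd(hr) - 3), 0.5)
  expect_lt(abs(mean(hr) - 70), 0.3)
})

test_that("HRV warm-up gap and carry-over behave as configured", {
  cfg <- quiet_config(data.frame(task_code = c("ET", "EO"), duration_s = c(300, 300)),
                      hrv_warmup_s = 120, carryover_halflife_s = 60)
  stream <- generate_eva(cfg, 1, "ID", 1)$stream
  expect_true(all(is.na(stream$hrv_ms[1:120])))
  expect_true(all(!is.na(stream$hrv_ms[121:600])))
  # noiseless: EO seconds right after ET carry a decaying ET residual
  eo_hr <- stream$hr_bpm[301:600]
  expect_gt(eo_hr[1], eo_hr[300])
  eff <- default_task_effect()
  expect_equal(eo_hr[60], 70 + eff["EO", "HR"] + eff["ET", "HR"] * 2^(-60 / 60),
               tolerance = 0.06)  # values rounded to 0.1
  expect_equal(eo_hr[300], 70 + eff["EO", "HR"], tolerance = 0.06)
})

test_that("jittered log shifts transitions by at most the jitter plus minute rounding", {
  cfg <- quiet_config(
    data.frame(task_code = c("Base", "ET", "EO", "ET", "EO"),
               duration_s = c(600, 300, 240, 300, 240)),
    label_jitter_s = 60, seed = 31
  )
  eva <- generate_eva(cfg, 1, "ID", 1)
  total <- sum(eva$true_log$end_s - eva$true_log$start_s)
  truth_per_s <- rep(eva$true_log$task_code, eva$true_log$end_s - eva$true_log$start_s)
  ann <- annotate(eva$stream, eva$jittered_log)
  mislabeled <- mean(ann$task_code != truth_per_s, na.rm = TRUE)
  n_trans <- nrow(eva$true_log) - 1
  expect_lte(mislabeled, 2 * 60 * n_trans / total)
  expect_true(all(eva$jittered_log$start_s[-1] %% 60 == 0))
})

test_that("default campaign reproduces the study shape and is seed-deterministic", {
  cmp <- small_campaign()
  # default-shape check on the shipped defaults, without writing all 28 files:
  cfg <- scenario_config(seed = 1)
  n_pairs <- sum(lengths(cfg$deployments_per_participant))
  expect_equal(cfg$n_participants, 8)
  expect_equal(n_pairs * cfg$evas_per_deployment, 28)
  expect_setequal(unlist(cfg$deployments_per_participant), eva_deployment_codes())
  expect_equal(sum(lengths(cfg$deployments_per_participant) == 3), 2)
  expect_equal(sum(lengths(cfg$deployments_per_participant) == 2), 2)
  expect_equal(sum(lengths(cfg$deployments_per_participant) == 1), 4)

  # regenerate the small campaign: identical bytes
  dir2 <- file.path(tempdir(), "evaphys-dup-campaign")
  unlink(dir2, recursive = TRUE)
  generate_campaign(cmp$config, dir2)
  f1 <- list.files(cmp$dir, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(dir2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(dir2, recursive = TRUE)
})

test_that("single-EVA campaign writes one manifest entry matching the schedule", {
  sched <- data.frame(task_code = c("Base", "ET"), duration_s = c(120, 180))
  cfg <- quiet_config(sched)
  dir <- tempfile()
  campaign <- generate_campaign(cfg, dir)
  expect_equal(nrow(campaign$manifest), 1)
  stream <- read_stream(file.path(dir, campaign$manifest$stream_file[1]))
  expect_equal(nrow(stream), 300)
  unlink(dir, recursive = TRUE)
})
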