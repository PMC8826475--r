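stream_columns <- c("time_s", "hr_bpm", "rr_brpm", "hrv_ms", "hr_confidence")

#' Read a 1 Hz physiological stream file
#'
#' Parses the stream CSV dialect (`time_s,hr_bpm,rr_brpm,hrv_ms,hr_confidence`,
#' one row per second). Empty HRV fields become missing values. Row order is
#' preserved and validated: times must be strictly increasing on a whole-second
#' grid (gaps are allowed, duplicates are not) and HR confidence must lie in
#' `[0, 100]`.
#'
#' @param path Path to a stream CSV.
#' @return A tibble of per-second records.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(stream_columns, trimws(header))
  if (length(missing_cols)) {
    stopf("format error in %s: missing column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      time_s = readr::col_double(),
      hr_bpm = readr::col_double(),
      rr_brpm = readr::col_double(),
      hrv_ms = readr::col_double(),
      hr_confidence = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  validate_stream(x, path)
  x
}

validate_stream <- function(x, path = "<stream>") {
  d <- diff(x$time_s)
  if (any(d == 0)) {
    stopf("data error in %s: duplicated time_s at row %d", path, which(d == 0)[1] + 1L)
  }
  if (any(d < 0)) {
    stopf("data error in %s: non-monotone time_s at row %d", path, which(d < 0)[1] + 1L)
  }
  if (any(x$time_s %% 1 != 0)) {
    stopf("data error in %s: time_s must be whole seconds (row %d)",
          path, which(x$time_s %% 1 != 0)[1])
  }
  bad_conf <- !is.na(x$hr_confidence) & (x$hr_confidence < 0 | x$hr_confidence > 100)
  if (any(bad_conf)) {
    stopf("data error in %s: hr_confidence outside [0, 100] at row %d",
          path, which(bad_conf)[1])
  }
  invisible(x)
}

#' Read a task log and reconstruct task intervals
#'
#' Parses the task-log dialect (`time_s,participant,task_code,note`; one row
#' per task transition) into half-open `[start, end)` intervals: each
#' transition opens a task that runs until the next transition; the final task
#' runs until `end_s`.
#'
#' @param path Path to a task-log CSV.
#' @param end_s End time (s) of the final interval; default `Inf` (the last
#'   task extends to the end of whatever stream it is matched with).
#' @param clock_offset_s Seconds added to every logged time to align the
#'   observer's clock with the device clock (default 0).
#' @return A tibble of task intervals (`start_s`, `end_s`, `task_code`,
#'   `participant`).
#' @export
read_task_log <- function(path, end_s = Inf, clock_offset_s = 0) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      time_s = readr::col_double(),
      participant = readr::col_character(),
      task_code = readr::col_character(),
      note = readr::col_character()
    ),
    na = "NA",
    progress = FALSE
  )
  bad <- setdiff(unique(x$task_code), eva_task_codes())
  if (length(bad)) {
    stopf("data error in %s: unknown task code(s): %s", path, paste(bad, collapse = ", "))
  }
  if (is.unsorted(x$time_s, strictly = TRUE)) {
    stopf("data error in %s: transition times must be strictly increasing", path)
  }
  t <- x$time_s + clock_offset_s
  tibble::tibble(
    start_s = t,
    end_s = c(t[-1], end_s),
    task_code = x$task_code,
    participant = x$participant
  )
}

#' Annotate each second with the task being performed
#'
#' Labels every stream record with the task whose half-open `[start, end)`
#' interval contains its `time_s`; records covered by no interval get a
#' missing label. The boundary second belongs to the later task. Labelling is
#' a pure function of (`time_s`, log): filtering rows before or after
#' annotation never changes a surviving record's label.
#'
#' @param stream A tibble from [read_stream()].
#' @param log A tibble of task intervals from [read_task_log()] (columns
#'   `start_s`, `end_s`, `task_code`).
#' @return The stream with `task_code` (character, `NA` when untasked) and
#'   `interval_id` (ordinal of the covering log interval, `NA` when untasked)
#'   columns appended.
#' @export
annotate <- function(stream, log) {
  log <- log[order(log$start_s), ]
  if (nrow(log) > 1) {
    overlap <- which(log$start_s[-1] < log$end_s[-nrow(log)])
    if (length(overlap)) {
      i <- overlap[1]
      stopf(paste0(
        "data error: overlapping task intervals: [%s, %s) %s overlaps [%s, %s) %s"),
        format(log$start_s[i]), format(log$end_s[i]), log$task_code[i],
        format(log$start_s[i + 1]), format(log$end_s[i + 1]), log$task_code[i + 1])
    }
  }
  idx <- findInterval(stream$time_s, log$start_s)
  covered <- idx >= 1 & idx <= nrow(log)
  inside <- covered
  inside[covered] <- stream$time_s[covered] < log$end_s[idx[covered]]
  idx1 <- pmax(idx, 1L)   # zero indices (before the first interval) would drop
  out <- stream
  out$task_code <- ifelse(inside, log$task_code[idx1], NA_character_)
  out$interval_id <- ifelse(inside, idx1, NA_integer_)
  out
}

#' Drop records not associated with any EVA task
#'
#' Keeps exactly the records carrying a task label, preserving order. Data
#' collected outside logged tasks (EVA prep, the drive back from the field
#' site) are excluded from all analysis.
#'
#' @param labeled Output of [annotate()].
#' @return The labelled records with non-missing `task_code`.
#' @export
drop_untasked <- function(labeled) {
  out <- labeled[!is.na(labeled$task_code), ]
  if (nrow(out) == 0 && nrow(labeled) > 0) {
    warnf("no records carry a task label; downstream stages will be empty")
  }
  out
}

#' Apply the HR-confidence quality gate
#'
#' Removes whole records whose device-reported HR-confidence value falls below
#' the threshold. The gate applies jointly to HR, RR and HRV: the confidence
#' value rates the whole system, so a low-confidence second contributes to no
#' parameter. The boundary value is kept (readings *below* the threshold are
#' discarded).
#'
#' @param labeled A tibble of (labelled) stream records.
#' @param threshold_pct Confidence threshold in percent (default 50).
#' @return The surviving records, order preserved.
#' @export
filter_confidence <- function(labeled, threshold_pct = 50) {
  if (threshold_pct < 0 || threshold_pct > 100) {
    stopf("threshold_pct must lie in [0, 100]")
  }
  labeled[!is.na(labeled$hr_confidence) & labeled$hr_confidence >= threshold_pct, ]
}

#' Read a campaign manifest
#'
#' @param path Path to a manifest CSV with columns `participant`,
#'   `deployment`, `eva`, `stream_file`, `log_file` and optionally
#'   `clock_offset_s` (seconds added to log times per file; default 0). File
#'   paths are resolved relative to the manifest's directory.
#' @return A tibble with absolute file paths and a `clock_offset_s` column.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("participant", "deployment", "eva", "stream_file", "log_file")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols)) {
    stopf("format error in %s: missing column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  if (!"clock_offset_s" %in% names(m)) m$clock_offset_s <- 0
  m$clock_offset_s[is.na(m$clock_offset_s)] <- 0
  root <- dirname(normalizePath(path))
  m$stream_file <- file.path(root, m$stream_file)
  m$log_file <- file.path(root, m$log_file)
  m
}

#' Ingest a full campaign into one labelled table
#'
#' Reads every stream/log pair listed in a manifest, annotates each second
#' with its task, drops untasked records and applies the HR-confidence gate.
#'
#' @param manifest A manifest path or the tibble from [read_manifest()].
#' @param hr_confidence_min Confidence threshold in percent (default 50).
#' @return A tidy labelled tibble: `participant`, `deployment`, `eva`,
#'   `time_s`, `task_code`, `interval_id`, `hr_bpm`, `rr_brpm`, `hrv_ms`,
#'   `hr_confidence`.
#' @export
ingest_campaign <- function(manifest, hr_confidence_min = 50) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    stream <- read_stream(manifest$stream_file[i])
    log <- read_task_log(manifest$log_file[i],
                         clock_offset_s = manifest$clock_offset_s[i])
    labeled <- annotate(stream, log)
    labeled$participant <- manifest$participant[i]
    labeled$deployment <- manifest$deployment[i]
    labeled$eva <- manifest$eva[i]
    labeled
  })
  labeled <- dplyr::bind_rows(rows)
  labeled <- drop_untasked(labeled)
  labeled <- filter_confidence(labeled, hr_confidence_min)
  dplyr::select(
    labeled,
    "participant", "deployment", "eva", "time_s", "task_code", "interval_id",
    "hr_bpm", "rr_brpm", "hrv_ms", "hr_confidence"
  )
}
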