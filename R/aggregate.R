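#' Segment labelled records into contiguous task occurrences
#'
#' A task occurrence is one contiguous episode of one task within one EVA —
#' the analysis unit. Maximal runs of consecutive surviving seconds sharing a
#' task label form one occurrence; a change of label always splits. Gaps
#' created purely by confidence-filtered seconds do **not** split an
#' occurrence: the episode is defined by the task, not by data continuity
#' (splitting on dropout seconds would inflate the occurrence count and
#' re-introduce serial dependence). When the `interval_id` column from
#' [annotate()] is present it is used to keep same-task episodes separated by
#' a fully dropped different-task span apart; otherwise run-length encoding on
#' the labels is used.
#'
#' @param labeled A labelled tibble (e.g. from [ingest_campaign()]), sorted by
#'   time within EVA, with at least `task_code`; optionally `participant`,
#'   `deployment`, `eva`, `interval_id`.
#' @return The input with `occurrence_id` (unique across the table) and
#'   `occurrence_index` (ordinal within participant-deployment-EVA) appended.
#' @export
segment_occurrences <- function(labeled) {
  if (nrow(labeled) == 0) {
    labeled$occurrence_id <- integer(0)
    labeled$occurrence_index <- integer(0)
    return(labeled)
  }
  keys <- intersect(c("participant", "deployment", "eva"), names(labeled))
  grp <- if (length(keys)) {
    do.call(paste, c(labeled[keys], sep = "\r"))
  } else {
    rep("all", nrow(labeled))
  }
  ord <- order(grp, labeled$time_s %||% seq_len(nrow(labeled)))
  x <- labeled[ord, ]
  g <- grp[ord]

  new_grp <- c(TRUE, g[-1] != g[-length(g)])
  if ("interval_id" %in% names(x) && !anyNA(x$interval_id)) {
    marker <- x$interval_id
  } else {
    marker <- match(x$task_code, unique(x$task_code))
  }
  new_run <- c(TRUE, marker[-1] != marker[-length(marker)] |
                 x$task_code[-1] != x$task_code[-nrow(x)])
  x$occurrence_id <- cumsum(new_grp | new_run)
  # ordinal within group
  first_of_grp <- stats::ave(x$occurrence_id, g, FUN = min)
  x$occurrence_index <- x$occurrence_id - first_of_grp + 1L
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse occurrences to per-parameter means
#'
#' Computes the arithmetic mean of the non-missing values of each parameter
#' over each occurrence — one mean response per task occurrence, the unit on
#' which all downstream inference runs. HRV occurrences with fewer than `hrv_min_samples`
#' valid seconds are suppressed (the device needs a minimum run of readings
#' for a within-task HRV estimate; short tasks therefore yield HR/RR means but
#' no HRV mean). Occurrences with zero valid values for a parameter are
#' suppressed with a message, never an error.
#'
#' @param segmented Output of [segment_occurrences()].
#' @param parameters Parameters to aggregate (default `HR`, `RR`, `HRV`).
#' @param hrv_min_samples Minimum valid seconds for an HRV occurrence mean
#'   (default 60, one minute at 1 Hz).
#' @return A tibble of occurrence means: `participant`, `deployment`, `eva`,
#'   `task_code`, `occurrence_index`, `parameter`, `mean_value`, `n_samples`.
#' @export
occurrence_means <- function(segmented, parameters = eva_parameters(),
                             hrv_min_samples = 60) {
  if (nrow(segmented) == 0) stopf("data error: no occurrences to aggregate")
  keys <- intersect(c("participant", "deployment", "eva"), names(segmented))

  cols <- vapply(parameters, param_column, "")
  long <- tidyr::pivot_longer(
    segmented,
    cols = dplyr::any_of(unname(cols)),
    names_to = "parameter", values_to = "value"
  )
  long$parameter <- names(cols)[match(long$parameter, cols)]

  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(
      c(keys, "task_code", "occurrence_id", "occurrence_index", "parameter")))),
    mean_value = mean(.data$value, na.rm = TRUE),
    n_samples = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  suppressed_empty <- sum(out$n_samples == 0)
  suppressed_hrv <- sum(out$parameter == "HRV" & out$n_samples > 0 &
                          out$n_samples < hrv_min_samples)
  if (suppressed_empty > 0) {
    message(sprintf("occurrence_means: suppressed %d occurrence-parameter pair(s) with no valid samples",
                    suppressed_empty))
  }
  if (suppressed_hrv > 0) {
    message(sprintf("occurrence_means: suppressed %d HRV occurrence(s) below hrv_min_samples = %d",
                    suppressed_hrv, hrv_min_samples))
  }
  out <- out[out$n_samples >= 1 &
               !(out$parameter == "HRV" & out$n_samples < hrv_min_samples), ]
  out$mean_value <- as.numeric(out$mean_value)
  dplyr::arrange(
    dplyr::select(out, -"occurrence_id"),
    dplyr::across(dplyr::all_of(c(keys, "occurrence_index", "parameter")))
  )
}
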