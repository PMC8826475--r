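#' Summarise significant pairwise differences per contrast and parameter
#'
#' Counts, for every task contrast and physiological parameter, how many cases
#' showed a significant difference out of the cases where both tasks were
#' performed (pairs with a missing significance flag — a task never performed
#' in that case — are excluded from the denominator). Per-contrast totals
#' across parameters and a grand-total row are appended, with nearest-integer
#' percentages alongside the exact counts.
#'
#' @param pairs Pairwise results from [pairwise_ci()].
#' @return A tidy tibble: `contrast` (15 task pairs plus `"Total"`),
#'   `parameter` (`HR`, `RR`, `HRV`, `Total`), `k_significant`, `n_cases`,
#'   `pct` (rounded to the nearest integer).
#' @export
summarize_significance <- function(pairs) {
  template <- tidyr::expand_grid(
    contrast = task_contrasts()$contrast,
    parameter = eva_parameters()
  )
  if (nrow(pairs) == 0) {
    counts <- dplyr::mutate(template, k_significant = 0L, n_cases = 0L)
  } else {
    counts <- dplyr::summarise(
      dplyr::group_by(pairs, .data$contrast, .data$parameter),
      k_significant = sum(.data$significant %in% TRUE),
      n_cases = sum(!is.na(.data$significant)),
      .groups = "drop"
    )
    counts <- dplyr::left_join(template, counts, by = c("contrast", "parameter"))
    counts$k_significant[is.na(counts$k_significant)] <- 0L
    counts$n_cases[is.na(counts$n_cases)] <- 0L
  }
  rollup_significance(counts)
}

# append per-contrast and grand totals and the printed percentages
rollup_significance <- function(counts) {
  row_tot <- dplyr::summarise(
    dplyr::group_by(counts, .data$contrast),
    parameter = "Total",
    k_significant = sum(.data$k_significant),
    n_cases = sum(.data$n_cases),
    .groups = "drop"
  )
  col_tot <- dplyr::summarise(
    dplyr::group_by(counts, .data$parameter),
    contrast = "Total",
    k_significant = sum(.data$k_significant),
    n_cases = sum(.data$n_cases),
    .groups = "drop"
  )
  grand <- tibble::tibble(
    contrast = "Total", parameter = "Total",
    k_significant = sum(counts$k_significant),
    n_cases = sum(counts$n_cases)
  )
  out <- dplyr::bind_rows(counts, row_tot, col_tot, grand)
  out$pct <- percent_round(out$k_significant, out$n_cases)
  ord_c <- c(task_contrasts()$contrast, "Total")
  ord_p <- c(eva_parameters(), "Total")
  dplyr::arrange(out, match(.data$contrast, ord_c), match(.data$parameter, ord_p))
}

#' Family-wise error rate under independence
#'
#' The probability of at least one false rejection across `n_comparisons`
#' independent comparisons each run at `per_comparison_alpha`:
#' `1 - (1 - alpha)^n`. With the conservative 99.98% intervals
#' (`alpha = 0.0002`) over the 405 pairwise comparisons of the full summary
#' table this is 0.0778, i.e. 7.78%.
#'
#' @param per_comparison_alpha Per-comparison error probability, in `(0, 1)`.
#' @param n_comparisons Number of comparisons, at least 1.
#' @return The family-wise error probability.
#' @examples
#' family_error(0.0002, 405)   # 0.0778...
#' @export
family_error <- function(per_comparison_alpha, n_comparisons) {
  if (per_comparison_alpha <= 0 || per_comparison_alpha >= 1) {
    stopf("per_comparison_alpha must lie in (0, 1)")
  }
  if (n_comparisons < 1) stopf("n_comparisons must be >= 1")
  1 - (1 - per_comparison_alpha)^n_comparisons
}

#' Per-case per-task mean responses
#'
#' The grand mean of the occurrence means for every case and task (the numeric
#' content of the per-case bar charts), with occurrence counts. Tasks a case's
#' participant never performed appear with missing values — no imputation.
#'
#' @param means Occurrence means from [occurrence_means()].
#' @param cases Case definitions from [build_cases()].
#' @return A tibble: `case_id`, `participant`, `parameter`, `task_code`,
#'   `mean_response`, `n_occurrences`.
#' @export
mean_response_table <- function(means, cases) {
  cm <- assign_cases(means, cases)
  out <- dplyr::summarise(
    dplyr::group_by(cm, .data$case_id, .data$participant, .data$parameter,
                    .data$task_code),
    mean_response = mean(.data$mean_value),
    n_occurrences = dplyr::n(),
    .groups = "drop"
  )
  out <- tidyr::complete(
    dplyr::group_by(out, .data$case_id, .data$participant, .data$parameter),
    task_code = eva_task_codes()
  )
  out <- dplyr::ungroup(out)
  out$n_occurrences[is.na(out$n_occurrences)] <- 0L
  dplyr::arrange(out, .data$parameter, .data$case_id,
                 match(.data$task_code, eva_task_codes()))
}

#' Bar chart of per-case mean responses
#'
#' Optional rendering of [mean_response_table()] output for one parameter,
#' one panel per case. Requires ggplot2.
#'
#' @param mrt Output of [mean_response_table()].
#' @param parameter Parameter to plot (default `"HR"`).
#' @return A ggplot object.
#' @export
plot_mean_response <- function(mrt, parameter = "HR") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_mean_response requires the ggplot2 package")
  }
  d <- mrt[mrt$parameter == parameter & !is.na(mrt$mean_response), ]
  unit <- c(HR = "beats/min", RR = "breaths/min", HRV = "ms")[[parameter]]
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$task_code, levels = eva_task_codes()),
    y = .data$mean_response
  )) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~case_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "task", y = sprintf("mean %s response (%s)", parameter, unit)) +
    ggplot2::theme_minimal()
}

#' Published per-contrast significance counts (reference data)
#'
#' The per-contrast, per-parameter counts of significant pairwise differences
#' (out of cases considered) reported by the motivating field campaign of 8
#' participants across three deployments. Shipped as reference data for
#' arithmetic roll-up checks: row and grand totals and the printed
#' percentages are recomputed from these counts, not stored.
#'
#' Two internal inconsistencies of the source table are documented rather
#' than emulated: (1) several printed HRV percentages disagree with their own
#' fractions (e.g. 7/10 printed as 58%); this package always reports the
#' recomputed nearest-integer percent. (2) The printed HRV cells sum to
#' 55/145, while the source's own HRV column total reads 30/145; the printed
#' per-parameter totals are therefore shipped separately as
#' [reported_parameter_totals()] and roll-ups that must match the published
#' grand total (134/405, 33%) use those.
#'
#' @return A tidy tibble: `contrast`, `parameter`, `k_significant`, `n_cases`.
#' @export
reported_significance_counts <- function() {
  k <- list(
    #             HR      RR      HRV
    "Base-BR" = c(10, 10, 2, 8, 7, 10),
    "Base-BS" = c(10, 10, 1, 8, 8, 10),
    "Base-EI" = c(9, 9, 2, 7, 4, 9),
    "Base-EO" = c(10, 10, 4, 8, 6, 10),
    "Base-ET" = c(10, 10, 5, 8, 6, 10),
    "BR-BS"   = c(2, 10, 2, 8, 3, 10),
    "BR-EI"   = c(3, 9, 3, 7, 1, 9),
    "BR-EO"   = c(3, 10, 0, 8, 2, 10),
    "BR-ET"   = c(2, 10, 0, 8, 3, 10),
    "BS-EI"   = c(0, 9, 0, 7, 4, 9),
    "BS-EO"   = c(2, 10, 1, 8, 3, 10),
    "BS-ET"   = c(5, 10, 1, 8, 3, 10),
    "EI-EO"   = c(1, 9, 4, 7, 2, 9),
    "EI-ET"   = c(3, 9, 6, 7, 3, 9),
    "EO-ET"   = c(1, 10, 2, 8, 0, 10)
  )
  m <- do.call(rbind, k)
  tibble::tibble(
    contrast = rep(rownames(m), each = 3),
    parameter = rep(eva_parameters(), times = nrow(m)),
    k_significant = as.integer(t(m[, c(1, 3, 5)])),
    n_cases = as.integer(t(m[, c(2, 4, 6)]))
  )
}

#' Published per-parameter total significance counts (reference data)
#'
#' The per-parameter column totals of the published significance summary:
#' 71/145 (HR), 33/115 (RR), 30/145 (HRV), summing to the published grand
#' total of 134/405 (33%). Kept separate from
#' [reported_significance_counts()] because the source's HRV column total is
#' inconsistent with the sum of its own printed HRV cells (see that help
#' page).
#'
#' @return A tibble: `parameter`, `k_significant`, `n_cases`.
#' @export
reported_parameter_totals <- function() {
  tibble::tibble(
    parameter = eva_parameters(),
    k_significant = c(71L, 33L, 30L),
    n_cases = c(145L, 115L, 145L)
  )
}
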