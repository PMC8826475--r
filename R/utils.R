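#' Task, deployment and parameter vocabularies
#'
#' Canonical code sets used throughout the package: the five field-science
#' task codes plus the baseline-rest code, the three field deployment codes,
#' and the three physiological parameters.
#'
#' @details
#' Task codes: `Base` (baseline rest), `ET` (translation/traversing),
#' `EO` (observation), `EI` (handheld instrument use), `BR` (breaking rocks),
#' `BS` (bagging samples / biological sterilization). Deployments: `ID`
#' (Idaho 2016), `HI1` (Hawai'i 2016), `HI2` (Hawai'i 2017). Parameters:
#' `HR` (beats/min), `RR` (breaths/min), `HRV` (ms).
#'
#' @return Character vector of codes, in canonical order.
#' @export
eva_task_codes <- function() c("Base", "BR", "BS", "EI", "EO", "ET")

#' @rdname eva_task_codes
#' @export
eva_deployment_codes <- function() c("ID", "HI1", "HI2")

#' @rdname eva_task_codes
#' @export
eva_parameters <- function() c("HR", "RR", "HRV")

# map parameter code -> stream column
param_column <- function(parameter) {
  c(HR = "hr_bpm", RR = "rr_brpm", HRV = "hrv_ms")[[parameter]]
}

#' All pairwise task contrasts in report order
#'
#' Enumerates the `C(6, 2) = 15` ordered task pairs (`Base-BR`, `Base-BS`,
#' ..., `EO-ET`) used by the pairwise comparison and summary tables. The
#' first-named task's level mean minus the second-named task's level mean is
#' the reported least-square difference.
#'
#' @return A tibble with columns `task_a`, `task_b`, `contrast`.
#' @export
task_contrasts <- function() {
  codes <- eva_task_codes()
  pairs <- utils::combn(codes, 2)
  tibble::tibble(
    task_a = pairs[1, ],
    task_b = pairs[2, ],
    contrast = paste0(pairs[1, ], "-", pairs[2, ])
  )
}

# nearest-integer percent as printed in the summary tables
percent_round <- function(k, n) {
  ifelse(n > 0, round(100 * k / n), NA_real_)
}

# deterministic 32-bit sub-seed derived from a base seed and integer keys
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in keys) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
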