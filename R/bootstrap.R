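#' Bootstrap specification
#'
#' Settings for the non-parametric bootstrap one-way ANOVA. The default
#' replicate count (100,000) lets the 0.01% tails of the conservative 99.98%
#' percentile interval rest on at least 10 order statistics; a warning is
#' issued when the expected per-tail replicate count falls below 10.
#'
#' @param n_replicates Number of bootstrap replicates (default 100,000).
#' @param ci_level Confidence level in percent, in `(0, 100)` (default 99.98,
#'   chosen conservatively so the family error over many pairwise comparisons
#'   stays small; no p-values are produced).
#' @param seed Integer seed; identical data and spec give identical results.
#' @param resampling_scheme `"stratified-by-task"` (default) resamples
#'   occurrence means with replacement *within* each task stratum, so every
#'   replicate has exactly the original per-task sample sizes;
#'   `"pooled"` draws every stratum from the pooled case data (a sensitivity
#'   variant that breaks the task structure).
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_replicates = 1e5, ci_level = 99.98, seed = 1L,
                           resampling_scheme = c("stratified-by-task", "pooled")) {
  resampling_scheme <- match.arg(resampling_scheme)
  if (ci_level <= 0 || ci_level >= 100) stopf("ci_level must lie in (0, 100)")
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  tail_mass <- (100 - ci_level) / 200
  if (n_replicates * tail_mass < 10 - 1e-9) {
    warnf("bootstrap_spec: expected %.1f replicates per %.3g%% tail (fewer than 10); tail percentiles will be coarse",
          n_replicates * tail_mass, 100 * tail_mass)
  }
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      ci_level = ci_level,
      seed = as.integer(seed),
      resampling_scheme = resampling_scheme
    ),
    class = "bootstrap_spec"
  )
}

#' Observed least-square difference between two task levels
#'
#' The unweighted difference of task-level means over the occurrence means of
#' one case: `mean(task_a) - mean(task_b)` (the second-named task's level mean
#' subtracted from the first's, the sign convention of the pairwise tables).
#' Returns `NA` when either task was never performed in the case.
#'
#' @param means Occurrence means of one case and parameter (columns
#'   `task_code`, `mean_value`).
#' @param task_a,task_b Task codes.
#' @return The LSD in parameter units, or `NA` if a task is absent.
#' @export
observed_lsd <- function(means, task_a, task_b) {
  a <- means$mean_value[means$task_code == task_a]
  b <- means$mean_value[means$task_code == task_b]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  mean(a) - mean(b)
}

#' Draw one stratified bootstrap replicate
#'
#' Resamples occurrence means with replacement within each task stratum, so
#' the replicate has exactly the same number of data points per task (and in
#' total) as the original case. Uses the current RNG state.
#'
#' @param means Occurrence means of one case and parameter (columns
#'   `task_code`, `mean_value`), or a named list of numeric strata.
#' @return An object of the same shape as the input, resampled.
#' @export
bootstrap_replicate <- function(means) {
  if (is.data.frame(means)) {
    strata <- split(means$mean_value, means$task_code)
    res <- lapply(strata, function(x) x[sample.int(length(x), length(x), replace = TRUE)])
    out <- means
    out$mean_value <- unsplit(res, means$task_code)
    return(out)
  }
  lapply(means, function(x) x[sample.int(length(x), length(x), replace = TRUE)])
}

# bootstrap distribution of the stratum mean: length-B vector, chunked to
# bound the index-matrix memory
replicate_stratum_means <- function(x, B, chunk = 20000L) {
  n <- length(x)
  if (n == 1) return(rep(x, B))
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- sample.int(n, n * b, replace = TRUE)
    out[(done + 1):(done + b)] <- colMeans(matrix(x[idx], nrow = n, ncol = b))
    done <- done + b
  }
  out
}

#' Pairwise bootstrap confidence intervals for task differences
#'
#' The inferential core: per case and parameter, a non-parametric bootstrap
#' one-way ANOVA over the task levels. Each replicate resamples the occurrence
#' means (stratified by task, preserving per-task counts) and recomputes every
#' pairwise difference of task-level means; the equal-tailed percentile
#' interval of each difference at `ci_level` is reported, and a difference is
#' significant exactly when zero falls outside its interval. All 15 task pairs
#' are emitted per case; pairs involving a task the participant never
#' performed appear with missing estimates ("not performed").
#'
#' @param means Occurrence means, either of a single case (columns `task_code`,
#'   `mean_value`) or a full table carrying `case_id` and `parameter` columns
#'   (e.g. from [assign_cases()]), in which case every case-parameter group is
#'   analysed.
#' @param spec A [bootstrap_spec()].
#' @return A tibble of pairwise results: `case_id`, `parameter`, `contrast`,
#'   `task_a`, `task_b`, `lsd`, `ci_low`, `ci_high`, `significant`, `n_a`,
#'   `n_b`.
#' @export
pairwise_ci <- function(means, spec = bootstrap_spec()) {
  stopifnot(inherits(spec, "bootstrap_spec"))
  if (!"case_id" %in% names(means)) means$case_id <- 1L
  if (!"parameter" %in% names(means)) means$parameter <- "HR"
  groups <- dplyr::group_split(dplyr::group_by(means, .data$parameter, .data$case_id))
  out <- lapply(groups, function(g) {
    key <- derive_seed(spec$seed,
                       match(g$parameter[1], eva_parameters()),
                       as.integer(g$case_id[1]))
    restore <- local_rng(key)
    on.exit(restore())
    res <- pairwise_ci_one(g, spec)
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, case_id = g$case_id[1], parameter = g$parameter[1],
                  .before = 1)
  })
  dplyr::bind_rows(out)
}

# one case x parameter; assumes RNG already seeded
pairwise_ci_one <- function(g, spec) {
  strata <- split(g$mean_value, g$task_code)
  strata <- strata[lengths(strata) > 0]
  if (length(strata) < 2) {
    message(sprintf("pairwise_ci: case %s (%s) has fewer than 2 task levels; skipped",
                    format(g$case_id[1]), g$parameter[1]))
    return(NULL)
  }
  B <- spec$n_replicates
  pool <- unlist(strata, use.names = FALSE)
  rep_means <- lapply(names(strata), function(tk) {
    if (spec$resampling_scheme == "pooled") {
      # sensitivity variant: keep the stratum's n but draw from the case pool
      replicate_stratum_means_pooled(pool, length(strata[[tk]]), B)
    } else {
      replicate_stratum_means(strata[[tk]], B)
    }
  })
  names(rep_means) <- names(strata)

  tail <- (100 - spec$ci_level) / 200
  contrasts <- task_contrasts()
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    a <- contrasts$task_a[i]
    b <- contrasts$task_b[i]
    n_a <- length(strata[[a]])
    n_b <- length(strata[[b]])
    if (n_a == 0 || n_b == 0) {
      return(tibble::tibble(
        contrast = contrasts$contrast[i], task_a = a, task_b = b,
        lsd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        significant = NA, n_a = n_a, n_b = n_b
      ))
    }
    diffs <- rep_means[[a]] - rep_means[[b]]
    ci <- stats::quantile(diffs, c(tail, 1 - tail), names = FALSE, type = 7)
    tibble::tibble(
      contrast = contrasts$contrast[i], task_a = a, task_b = b,
      lsd = mean(strata[[a]]) - mean(strata[[b]]),
      ci_low = ci[1], ci_high = ci[2],
      significant = ci[1] > 0 || ci[2] < 0,
      n_a = n_a, n_b = n_b
    )
  })
  dplyr::bind_rows(rows)
}

replicate_stratum_means_pooled <- function(pool, n, B, chunk = 20000L) {
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- sample.int(length(pool), n * b, replace = TRUE)
    out[(done + 1):(done + b)] <- colMeans(matrix(pool[idx], nrow = n, ncol = b))
    done <- done + b
  }
  out
}
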