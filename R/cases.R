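#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the supremum distance `D` between the empirical CDFs of two
#' samples and a two-sided p-value. The default p-value uses the asymptotic
#' Kolmogorov distribution with the standard small-sample correction on the
#' effective sample size (`sqrt(ne) + 0.12 + 0.11/sqrt(ne)`); `method =
#' "exact"` delegates to the exact two-sample computation in
#' [stats::ks.test()]. Symmetric in its two arguments.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param method `"asymptotic"` (default, with small-sample correction) or
#'   `"exact"`.
#' @return A list with `statistic` (D, in `[0, 1]`) and `p.value`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    stopf("data error: both KS samples must be non-empty")
  }
  d <- unname(suppressWarnings(stats::ks.test(x, y))$statistic)
  p <- if (method == "exact") {
    unname(suppressWarnings(stats::ks.test(x, y, exact = TRUE))$p.value)
  } else {
    n <- length(x)
    m <- length(y)
    ne <- n * m / (n + m)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
    kolmogorov_q(lambda)
  }
  list(statistic = d, p.value = min(max(p, 0), 1))
}

# upper tail of the Kolmogorov distribution, Q(lambda) = 2 sum (-1)^{j-1} exp(-2 j^2 lambda^2)
kolmogorov_q <- function(lambda) {
  if (lambda < 1e-8) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}

#' Alpha level for the deployment-combination KS tests
#'
#' Participants observed in two deployments face a single two-sample
#' comparison, tested at `alpha_two`; participants in all three deployments
#' face three pairwise comparisons, each tested at `alpha_three` to hold the
#' family error rate near `alpha_two` (0.05/3 rounded to 0.017). One
#' deployment needs no test (`NA` is returned); more than three generalises to
#' `alpha_two / choose(n, 2)`.
#'
#' @param n_deployments Number of deployments with data for the participant.
#' @param alpha_two Per-test alpha for 2 deployments (default 0.05).
#' @param alpha_three Per-test alpha for 3 deployments (default 0.017).
#' @return A single alpha level, or `NA` when no test is needed.
#' @export
select_alpha <- function(n_deployments, alpha_two = 0.05, alpha_three = 0.017) {
  if (n_deployments < 1) stopf("n_deployments must be >= 1")
  if (n_deployments == 1) return(NA_real_)
  if (n_deployments == 2) return(alpha_two)
  if (n_deployments == 3) return(alpha_three)
  message(sprintf("select_alpha: %d deployments; using %g / choose(n, 2)",
                  n_deployments, alpha_two))
  alpha_two / choose(n_deployments, 2)
}

#' Assemble cases by pooling indistinguishable deployments
#'
#' For each participant and parameter, pools that participant's occurrence
#' means per deployment and runs pairwise two-sample KS tests at the
#' multiplicity-adjusted alpha from [select_alpha()]. Deployments whose
#' distributions are *not* significantly different may share a case; cases are
#' maximal cliques of the non-significance graph, assigned greedily by
#' descending combined number of means with a deterministic lexicographic
#' tie-break in deployment order (`ID < HI1 < HI2`). Deployments that differ
#' from everything become singleton cases. Combination decisions are made
#' separately per parameter and may disagree across parameters.
#'
#' @param means Occurrence means from [occurrence_means()].
#' @param alpha_two,alpha_three Alpha levels passed to [select_alpha()].
#' @param method KS p-value method, see [ks_two_sample()].
#' @return A tibble of case definitions: `case_id` (ordinal within parameter),
#'   `participant`, `parameter`, `deployments` (slash-joined, e.g. `ID/HI1`),
#'   `n_means`.
#' @export
build_cases <- function(means, alpha_two = 0.05, alpha_three = 0.017,
                        method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  stopifnot(all(c("participant", "deployment", "parameter", "mean_value") %in% names(means)))
  groups <- dplyr::group_split(dplyr::group_by(means, .data$participant, .data$parameter))
  defs <- lapply(groups, function(g) {
    deps <- intersect(eva_deployment_codes(), unique(g$deployment))
    samples <- lapply(deps, function(d) g$mean_value[g$deployment == d])
    names(samples) <- deps
    cliques <- combine_deployments(samples, alpha_two, alpha_three, method)
    tibble::tibble(
      participant = g$participant[1],
      parameter = g$parameter[1],
      deployments = vapply(cliques, paste, "", collapse = "/"),
      n_means = vapply(cliques, function(cl) sum(lengths(samples[cl])), 0L),
      first_dep = vapply(cliques, function(cl) match(cl[1], eva_deployment_codes()), 0L)
    )
  })
  out <- dplyr::bind_rows(defs)
  out <- dplyr::arrange(out, .data$parameter, .data$participant, .data$first_dep)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$parameter),
    case_id = dplyr::row_number(), .before = 1
  )
  dplyr::select(dplyr::ungroup(out), -"first_dep")
}

# partition deployment codes into maximal cliques of the KS non-significance
# graph, greedily by combined sample size, lexicographic tie-break
combine_deployments <- function(samples, alpha_two, alpha_three, method) {
  deps <- names(samples)
  k <- length(deps)
  if (k == 1) return(list(deps))
  alpha <- select_alpha(k, alpha_two, alpha_three)
  compat <- matrix(TRUE, k, k, dimnames = list(deps, deps))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- ks_two_sample(samples[[i]], samples[[j]], method = method)$p.value
      compat[i, j] <- compat[j, i] <- p >= alpha
    }
  }
  remaining <- deps
  cliques <- list()
  while (length(remaining)) {
    best <- NULL
    # candidate cliques: complete subsets of remaining, maximal within remaining
    subsets <- all_subsets(remaining)
    complete <- Filter(function(s) all(compat[s, s]), subsets)
    maximal <- Filter(function(s) {
      !any(vapply(complete, function(t) length(t) > length(s) && all(s %in% t), TRUE))
    }, complete)
    score <- vapply(maximal, function(s) sum(lengths(samples[s])), 0)
    ord <- order(-score, vapply(maximal, function(s) {
      paste(sprintf("%02d", sort(match(s, eva_deployment_codes()))), collapse = "")
    }, ""))
    best <- maximal[[ord[1]]]
    cliques <- c(cliques, list(best[order(match(best, eva_deployment_codes()))]))
    remaining <- setdiff(remaining, best)
  }
  cliques[order(vapply(cliques, function(cl) match(cl[1], eva_deployment_codes()), 0))]
}

all_subsets <- function(x) {
  unlist(lapply(seq_along(x), function(n) {
    m <- utils::combn(x, n)
    lapply(seq_len(ncol(m)), function(i) m[, i])
  }), recursive = FALSE)
}

#' Attach case ids to occurrence means
#'
#' Joins the case definitions from [build_cases()] back onto the occurrence
#' means, so every mean carries the `case_id` whose deployment set contains
#' its deployment (per participant and parameter).
#'
#' @param means Occurrence means from [occurrence_means()].
#' @param cases Case definitions from [build_cases()].
#' @return `means` with a `case_id` column.
#' @export
assign_cases <- function(means, cases) {
  lut <- tidyr::separate_rows(cases, "deployments", sep = "/")
  lut <- dplyr::rename(lut, deployment = "deployments")
  out <- dplyr::inner_join(
    means, lut[, c("case_id", "participant", "parameter", "deployment")],
    by = c("participant", "parameter", "deployment")
  )
  if (nrow(out) != nrow(means)) {
    warnf("assign_cases: %d occurrence mean(s) matched no case and were dropped",
          nrow(means) - nrow(out))
  }
  out
}
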