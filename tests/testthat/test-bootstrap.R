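test_that("bootstrap spec validates its inputs and warns on coarse tails", {
  expect_error(bootstrap_spec(ci_level = 0), "ci_level")
  expect_error(bootstrap_spec(ci_level = 100), "ci_level")
  expect_error(bootstrap_spec(n_replicates = 1), "n_replicates")
  expect_warning(bootstrap_spec(n_replicates = 2000, ci_level = 99.98), "coarse")
  expect_silent(spec <- bootstrap_spec(n_replicates = 1e5, ci_level = 99.98))
  expect_equal(spec$n_replicates, 100000L)
})

test_that("observed LSD is the first task's level mean minus the second's", {
  means <- make_means(list(ET = c(10, 20), EO = 5))
  expect_equal(observed_lsd(means, "ET", "EO"), 10)
  expect_equal(observed_lsd(means, "EO", "ET"), -10)
  expect_equal(observed_lsd(means, "ET", "ET"), 0)
  expect_true(is.na(observed_lsd(means, "ET", "BR")))
})

test_that("stratified replicates conserve per-task counts", {
  means <- make_means(list(ET = rnorm(7), EO = rnorm(3), BR = 4.4))
  set.seed(1)
  rep1 <- bootstrap_replicate(means)
  expect_equal(table(rep1$task_code), table(means$task_code))
  expect_equal(nrow(rep1), nrow(means))
  # size-1 stratum: the single value is drawn with certainty
  expect_equal(rep1$mean_value[rep1$task_code == "BR"], 4.4)
  # resampled values come from the right stratum
  expect_true(all(rep1$mean_value[rep1$task_code == "ET"] %in%
                    means$mean_value[means$task_code == "ET"]))
})

test_that("replicate stratum means match exhaustive enumeration on 3 points", {
  x <- c(1, 2, 4)
  grid <- expand.grid(x, x, x)
  enum <- rowMeans(grid)                      # 27 equally likely outcomes
  tab <- table(round(enum, 10)) / 27
  set.seed(33)
  draws <- round(evaphys:::replicate_stratum_means(x, 20000), 10)
  obs <- table(factor(draws, levels = names(tab)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = as.numeric(tab)))
  expect_gt(gof$p.value, 0.01)
})

test_that("degenerate data give zero LSDs, zero-width CIs, no significance", {
  means <- make_means(list(ET = rep(5, 4), EO = rep(5, 3), Base = rep(5, 6)))
  res <- suppressWarnings(pairwise_ci(means, bootstrap_spec(n_replicates = 500, seed = 2)))
  done <- res[!is.na(res$lsd), ]
  expect_equal(nrow(done), 3)
  expect_true(all(done$lsd == 0))
  expect_true(all(done$ci_low == 0 & done$ci_high == 0))
  expect_false(any(done$significant))
})

test_that("all 15 contrasts are emitted, absent tasks as 'not performed' rows", {
  vals <- list(Base = rnorm(5, 70), BR = rnorm(5, 95), BS = rnorm(5, 85),
               EO = rnorm(5, 88), ET = rnorm(5, 95))   # EI never performed
  means <- make_means(vals)
  res <- suppressWarnings(pairwise_ci(means, bootstrap_spec(n_replicates = 400, seed = 3)))
  expect_equal(nrow(res), 15)
  expect_equal(res$contrast, task_contrasts()$contrast)
  ei_rows <- res[res$task_a == "EI" | res$task_b == "EI", ]
  expect_equal(nrow(ei_rows), 5)
  expect_true(all(is.na(ei_rows$lsd) & is.na(ei_rows$significant)))
  expect_true(all(ei_rows$n_a == 0 | ei_rows$n_b == 0))
  full <- make_means(lapply(setNames(eva_task_codes(), eva_task_codes()),
                            function(t) rnorm(4, 80)))
  res_full <- suppressWarnings(pairwise_ci(full, bootstrap_spec(n_replicates = 400, seed = 3)))
  expect_equal(sum(!is.na(res_full$lsd)), 15)
})

test_that("results are deterministic in (data, spec) and CIs nest across levels", {
  set.seed(11)
  means <- make_means(list(Base = rnorm(10, 70), ET = rnorm(12, 90),
                           EO = rnorm(8, 85)))
  spec90 <- bootstrap_spec(n_replicates = 4000, ci_level = 90, seed = 7)
  spec99 <- bootstrap_spec(n_replicates = 4000, ci_level = 99, seed = 7)
  r90a <- pairwise_ci(means, spec90)
  r90b <- pairwise_ci(means, spec90)
  expect_identical(r90a, r90b)
  r99 <- pairwise_ci(means, spec99)
  done <- !is.na(r90a$lsd)
  expect_true(all(r99$ci_low[done] <= r90a$ci_low[done]))
  expect_true(all(r99$ci_high[done] >= r90a$ci_high[done]))
})

test_that("swapping a contrast's tasks negates the LSD and keeps significance", {
  set.seed(19)
  means <- make_means(list(BR = rnorm(20, 95, 3), BS = rnorm(20, 85, 3),
                           ET = rnorm(20, 95.5, 3)))
  spec <- bootstrap_spec(n_replicates = 6000, ci_level = 95, seed = 5)
  res <- pairwise_ci(means, spec)
  # relabel BR <-> BS: the BR-BS contrast must mirror
  swapped <- means
  swapped$task_code <- c(BR = "BS", BS = "BR", ET = "ET")[means$task_code]
  res_sw <- pairwise_ci(swapped, spec)
  ab <- res[res$contrast == "BR-BS", ]
  ba <- res_sw[res_sw$contrast == "BR-BS", ]
  expect_equal(ba$lsd, -ab$lsd)
  expect_equal(ba$significant, ab$significant)   # well-separated pair
  expect_equal(ba$ci_low, -ab$ci_high, tolerance = 0.25)
  expect_equal(ba$ci_high, -ab$ci_low, tolerance = 0.25)
  # overlapping pair stays non-significant under relabelling too
  ab2 <- res[res$contrast == "BR-ET", ]
  expect_false(ab2$significant)
})

test_that("well-separated tasks are detected at the conservative level", {
  set.seed(8)
  hits <- vapply(1:100, function(i) {
    means <- make_means(list(ET = rnorm(25, 100, 2), EI = rnorm(25, 80, 2)))
    spec <- suppressWarnings(bootstrap_spec(n_replicates = 2000, ci_level = 99.98,
                                            seed = i))
    res <- suppressWarnings(pairwise_ci(means, spec))
    res$significant[res$contrast == "EI-ET"]
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("pooled resampling variant runs and reports the same observed LSDs", {
  set.seed(14)
  means <- make_means(list(ET = rnorm(10, 90), EO = rnorm(10, 85)))
  spec_s <- bootstrap_spec(n_replicates = 1000, ci_level = 95, seed = 4)
  spec_p <- bootstrap_spec(n_replicates = 1000, ci_level = 95, seed = 4,
                           resampling_scheme = "pooled")
  rs <- pairwise_ci(means, spec_s)
  rp <- pairwise_ci(means, spec_p)
  expect_equal(rs$lsd, rp$lsd)
  done <- !is.na(rp$lsd)
  expect_true(all(rp$ci_low[done] <= rp$ci_high[done]))
})
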