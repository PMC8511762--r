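# Reward rate, optimal thresholds, and the posterior predictive
# optimal-threshold summaries.

test_that("reward rate matches the closed-form oracle", {
  got <- reward_rate(a = 1, v = 1, ter = 0.3, timing = trial_timing(1))
  expect_equal(got, (1 / (1 + exp(-1))) / (0.5 * tanh(0.5) + 1.3),
               tolerance = 1e-12)
  # reward rate vanishes as overhead grows without bound
  expect_lt(reward_rate(1, 1, 0.3, trial_timing(1e9)), 1e-8)
  expect_error(reward_rate(1, v = -1, ter = 0.3), class = "rrddm_param_error")
  expect_error(reward_rate(-1, v = 1, ter = 0.3), class = "rrddm_param_error")
})

test_that("optimal threshold matches exhaustive grid search", {
  combos <- expand.grid(v = c(0.5, 1, 1.5, 2, 3),
                        ter = c(0.1, 0.3, 0.5, 0.8),
                        overhead = c(0.2, 0.5, 1, 2, 4))
  grid <- seq(1e-3, 10, by = 1e-3)
  for (i in seq_len(nrow(combos))) {
    v <- combos$v[i]; ter <- combos$ter[i]
    tm <- trial_timing(combos$overhead[i])
    a_star <- optimal_threshold(v, ter, tm)
    a_grid <- grid[which.max(reward_rate(grid, v, ter, tm))]
    expect_lt(abs(a_star - a_grid), 2e-3)
    # the optimum beats nearby alternatives
    expect_gte(reward_rate(a_star, v, ter, tm),
               reward_rate(0.5 * a_star, v, ter, tm) - 1e-9)
    expect_gte(reward_rate(a_star, v, ter, tm),
               reward_rate(2 * a_star, v, ter, tm) - 1e-9)
  }
})

test_that("optimal threshold is non-decreasing in overhead", {
  overheads <- c(0.1, 0.25, 0.5, 1, 2, 4)
  for (v in c(0.5, 1.5, 3)) {
    for (ter in c(0.1, 0.4)) {
      a_stars <- vapply(overheads, function(o) {
        optimal_threshold(v, ter, trial_timing(o))
      }, numeric(1))
      expect_true(all(diff(a_stars) >= -1e-6))
    }
  }
})

test_that("the optimum collapses to zero as total dead time vanishes", {
  a_star <- optimal_threshold(1, ter = 0, timing = trial_timing(0))
  expect_lt(a_star, 0.06)
  expect_error(optimal_threshold(-1, 0.3), class = "rrddm_param_error")
})

test_that("optimal threshold is continuous in drift", {
  vs <- seq(0.5, 3, by = 0.01)
  a_stars <- optimal_threshold(vs, ter = 0.3, timing = trial_timing(1))
  expect_lt(max(abs(diff(a_stars))), 0.05)  # no grid artefacts
})

test_that("posterior predictive optimal threshold summarises draws", {
  # degenerate posterior: identical draws give identical a*
  deg <- tibble::tibble(v = rep(1.5, 1000), ter = rep(0.3, 1000))
  out <- posterior_predictive_optimal(deg, trial_timing(1))
  expect_equal(max(out$samples$a_star), min(out$samples$a_star))
  expect_identical(out$n_excluded, 0L)

  draws <- withr::with_seed(9, tibble::tibble(v = rlnorm(1000, 0.5, 0.3),
                                              ter = runif(1000, 0.2, 0.4)))
  out <- posterior_predictive_optimal(draws, trial_timing(1))
  s <- out$summary
  expect_true(s$opt_q04 <= s$opt_median && s$opt_median <= s$opt_q06)
  expect_true(all(c(s$opt_q02, s$opt_q04) <= s$opt_median))
  # bands reproduce a direct per-draw computation
  direct <- optimal_threshold(draws$v, draws$ter, trial_timing(1))
  expect_equal(s$opt_median, median(direct), tolerance = 1e-9)
  expect_equal(s$opt_q02, unname(quantile(direct, 0.2)), tolerance = 1e-9)

  # non-positive drift draws are flagged and excluded
  bad <- dplyr::bind_rows(draws, tibble::tibble(v = c(-1, 0), ter = 0.3))
  out2 <- posterior_predictive_optimal(bad, trial_timing(1))
  expect_identical(out2$n_excluded, 2L)
})

test_that("threshold-optimality table has one row per block with true medians", {
  d <- generate_dataset(quick_design(n_per_group = 2, n_blocks = 3,
                                     fixed_trials = 20), seed = 51)
  dp <- apply_exclusions(d, exclusion_config(drop_first_block = FALSE,
                                             min_eligible_trials = 10))
  fit <- suppressWarnings(
    fit_ddm(dp, "block_threshold", config = quick_config(), seed = 3,
            warn_rhat = Inf)
  )
  tab <- threshold_optimality_table(fit, trial_timing(1), seed = 4)
  expect_identical(nrow(tab), 2L * 3L)  # two groups x three blocks
  # medians equal direct quantile computation on the raw draws
  m <- posterior_matrix(fit$samples)
  row1 <- tab[tab$group == "fixed_time" & tab$block == 1, ]
  expect_equal(row1$median, median(m[, "mu_a[fixed_time,1]"]))
  expect_equal(row1$ci_low,
               unname(quantile(m[, "mu_a[fixed_time,1]"], 0.025)))
  # bands are monotone
  expect_true(all(tab$opt_q02 <= tab$opt_q04 & tab$opt_q04 <= tab$opt_q06 &
                    tab$opt_q06 <= tab$opt_q08))
  # determinism of the predictive draw
  tab2 <- threshold_optimality_table(fit, trial_timing(1), seed = 4)
  expect_identical(tab$opt_median, tab2$opt_median)
  # autoplot returns a ggplot without error
  expect_s3_class(autoplot(tab), "ggplot")
})

test_that("optimal threshold is consistent across diffusion scalings", {
  # (v, s) and (c v, c s) describe the same process up to evidence units:
  # a* scales by c and the predicted accuracy at a* is unchanged
  tm <- trial_timing(1)
  a1 <- optimal_threshold(1.2, 0.3, tm, s = 1)
  a2 <- optimal_threshold(0.12, 0.3, tm, s = 0.1)
  expect_equal(a2, 0.1 * a1, tolerance = 1e-4)
  acc1 <- choice_probability(ddm_params(1.2, a1, 0.5, s = 1))
  acc2 <- choice_probability(ddm_params(0.12, a2, 0.5, s = 0.1))
  expect_equal(acc1, acc2, tolerance = 1e-6)
})
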