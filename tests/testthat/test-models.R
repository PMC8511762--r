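# Hierarchical model specs: enumeration oracles for the parameter
# inventories, packing, and the joint log posterior against a component-sum
# oracle.

# independent enumeration of the expected free-parameter count
count_block_model <- function(P_per_group, n_groups, B, drift_by_block) {
  ind_per_p <- if (drift_by_block) 2 + 2 * B else 3 + B
  hyper_per_g <- if (drift_by_block) 4 + 4 * B else 6 + 2 * B
  as.integer(n_groups * (P_per_group * ind_per_p + hyper_per_g))
}

test_that("block-threshold spec matches the enumeration oracle", {
  spec <- spec_block_threshold(two_participants(), blocks = 1:3)
  expect_identical(n_free_parameters(spec), count_block_model(2, 1, 3, FALSE))
  expect_identical(n_free_parameters(spec), 24L)
  # only thresholds are block-indexed
  blk <- spec$pars[!is.na(spec$pars$block) & spec$pars$role == "individual", ]
  expect_true(all(blk$param == "a"))
  # B = 1 reduces to a constant-threshold model
  spec1 <- spec_block_threshold(two_participants(), blocks = 1)
  expect_identical(n_free_parameters(spec1), count_block_model(2, 1, 1, FALSE))
})

test_that("block-drift robustness spec matches the enumeration oracle", {
  spec <- spec_block_threshold_drift(two_participants(), blocks = 1:3)
  expect_identical(n_free_parameters(spec), count_block_model(2, 1, 3, TRUE))
  blk <- spec$pars[!is.na(spec$pars$block) & spec$pars$role == "individual", ]
  expect_setequal(unique(blk$param), c("a", "v"))
})

test_that("optimality-offset spec matches the enumeration oracle", {
  spec <- spec_optimality_offset(two_participants())
  # per participant v, ter, c; group level mu/sigma for v, ter plus mu_c, sigma_c
  expect_identical(n_free_parameters(spec), 2L * 3L + 6L)
  expect_identical(spec$blocks, 11:20)
  expect_false(any(spec$pars$param == "zr"))  # zr fixed at 0.5
  expect_error(spec_optimality_offset(mini_trials()),
               class = "rrddm_spec_error")
})

test_that("group-difference spec matches the enumeration oracle", {
  parts <- dplyr::bind_rows(two_participants("fixed_time"),
                            tibble::tibble(participant_id = c("q1", "q2"),
                                           group = "fixed_trial"))
  spec <- spec_group_difference(parts)
  # 12 individual + 8 group-level v/ter + mu_c_bar + delta_c + 2 sigma_c
  expect_identical(n_free_parameters(spec), 12L + 8L + 4L)
  expect_true(all(c("mu_c_bar", "delta_c") %in% spec$pars$name))
})

test_that("pack/unpack round-trips the flat vector", {
  spec <- spec_block_threshold(two_participants(), blocks = 1:2)
  vals <- stats::setNames(seq_len(n_free_parameters(spec)) / 10,
                          spec$pars$name)
  theta <- pack_parameters(spec, sample(vals))  # order-insensitive input
  expect_identical(unname(theta), unname(vals[spec$pars$name]))
  back <- unpack_parameters(spec, theta)
  expect_identical(back$value, unname(theta))
  expect_error(pack_parameters(spec, vals[-1]), class = "rrddm_packing_error")
  expect_error(log_posterior(spec, mini_trials(blocks = 1:2), theta[-1]),
               class = "rrddm_packing_error")
})

# a valid parameter vector centred in the prior ranges
reference_theta <- function(spec) {
  p <- spec$pars
  val <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    val[i] <- switch(
      p$param[i],
      mu_v = 1.8, sigma_v = 0.4, v = 1.9,
      mu_zr = 0.5, sigma_zr = 0.05, zr = 0.52,
      mu_ter = 0.3, sigma_ter = 0.05, ter = 0.28,
      mu_a = 1.4, sigma_a = 0.3, a = 1.5,
      mu_c = 0.2, sigma_c = 0.3, c = 0.1,
      mu_c_bar = 0.2, delta_c = 0.1,
      stop("unmapped ", p$param[i])
    )
  }
  stats::setNames(val, p$name)
}

test_that("log posterior equals the independent component-sum oracle", {
  d <- mini_trials(n_per_block = 6, blocks = 1:2)
  d1 <- d[d$participant_id == "p1", ]
  spec <- spec_block_threshold(d1, blocks = 1:2)
  theta <- reference_theta(spec)
  got <- log_posterior(spec, d1, theta)

  # oracle: hyperpriors + individual truncated-normal priors + likelihood,
  # each computed with the public closed-form pieces
  p <- spec$pars
  hyp <- p[p$role == "hyper", ]
  lp_h <- sum(rrddm:::dtnorm_log(theta[hyp$name], hyp$prior_loc,
                                 hyp$prior_scale, hyp$prior_lower,
                                 hyp$prior_upper))
  ind <- p[p$role == "individual", ]
  lp_i <- sum(rrddm:::dtnorm_log(theta[ind$name], theta[ind$hyper_loc],
                                 theta[ind$hyper_scale], ind$lower,
                                 ind$upper))
  lp_l <- 0
  for (b in 1:2) {
    db <- d1[d1$block == b, ]
    lp_l <- lp_l + ddm_log_likelihood(
      db, ddm_params(v = theta["v[p1]"], a = theta[sprintf("a[p1,%d]", b)],
                     zr = theta["zr[p1]"], ter = theta["ter[p1]"])
    )
  }
  expect_equal(got, lp_h + lp_i + lp_l, tolerance = 1e-10)
  # deterministic: bit-identical on re-evaluation
  expect_identical(got, log_posterior(spec, d1, theta))
})

test_that("log posterior is -Inf outside truncation bounds", {
  d <- mini_trials(blocks = 1:2)
  spec <- spec_block_threshold(d, blocks = 1:2)
  theta <- reference_theta(spec)
  bad <- theta
  bad["zr[p1]"] <- 0.95  # outside the (0.2, 0.8) individual domain
  expect_identical(log_posterior(spec, d, bad), -Inf)
  bad <- theta
  bad["sigma_v[fixed_time]"] <- -0.1
  expect_identical(log_posterior(spec, d, bad), -Inf)
})

test_that("offset model's deterministic node places thresholds at a* + c", {
  d <- mini_trials(n_per_block = 4, blocks = 11:12)
  d1 <- d[d$participant_id == "p1", ]
  spec <- spec_optimality_offset(d1, timing = trial_timing(1),
                                 blocks = 11:12)
  theta <- reference_theta(spec)
  theta["c[p1]"] <- 0
  got <- log_posterior(spec, d1, theta)
  p <- spec$pars
  hyp <- p[p$role == "hyper", ]
  lp_h <- sum(rrddm:::dtnorm_log(theta[hyp$name], hyp$prior_loc,
                                 hyp$prior_scale, hyp$prior_lower,
                                 hyp$prior_upper))
  ind <- p[p$role == "individual", ]
  lp_i <- sum(rrddm:::dtnorm_log(theta[ind$name], theta[ind$hyper_loc],
                                 theta[ind$hyper_scale], ind$lower,
                                 ind$upper))
  a_star <- optimal_threshold(theta["v[p1]"], theta["ter[p1]"],
                              trial_timing(1))
  lp_l <- ddm_log_likelihood(
    d1, ddm_params(v = theta["v[p1]"], a = a_star, zr = 0.5,
                   ter = theta["ter[p1]"])
  )
  expect_equal(got, lp_h + lp_i + lp_l, tolerance = 1e-6)
})

test_that("group-difference model ties the offset means to mu_c_bar +/- delta_c/2", {
  d <- mini_trials(n_per_block = 4, blocks = 11:12)
  spec <- spec_group_difference(d, blocks = 11:12)
  theta <- reference_theta(spec)
  # delta_c = 0: both groups share mu_c; shifting mu_c_bar by +x and
  # delta_c by +2x moves only the fixed_time group's implied mean
  t0 <- theta; t0["delta_c"] <- 0
  lp0 <- log_posterior(spec, d, t0)
  expect_true(is.finite(lp0))
  # symmetric construction: (mu_c_bar, delta_c) -> implied group means
  t1 <- theta; t1["mu_c_bar"] <- 0.3; t1["delta_c"] <- 0.2
  t2 <- theta; t2["mu_c_bar"] <- 0.3; t2["delta_c"] <- -0.2
  # swapping the sign of delta_c must swap the groups' prior terms only;
  # with group-symmetric data and individual values, lp is unchanged when
  # the individual c values are swapped between groups accordingly
  t2[c("c[p1]", "c[p2]")] <- t1[c("c[p2]", "c[p1]")]
  # p1 is fixed_time, p2 is fixed_trial and data are not identical, so only
  # check finiteness and that delta_c enters the density at all
  expect_true(is.finite(log_posterior(spec, d, t1)))
  t3 <- theta; t3["delta_c"] <- 5
  expect_false(isTRUE(all.equal(log_posterior(spec, d, theta),
                                log_posterior(spec, d, t3))))
})

test_that("block-threshold and robustness models coincide at B = 1", {
  d <- mini_trials(n_per_block = 8, blocks = 1)
  s1 <- spec_block_threshold(d, blocks = 1)
  s2 <- spec_block_threshold_drift(d, blocks = 1)
  expect_identical(n_free_parameters(s1), n_free_parameters(s2))
  theta1 <- reference_theta(s1)
  # map values across the naming difference (v[p] <-> v[p,1]; mu_v <-> mu_v[g,1])
  theta2 <- stats::setNames(numeric(n_free_parameters(s2)), s2$pars$name)
  for (nm in names(theta2)) {
    nm1 <- if (nm %in% names(theta1)) nm else sub(",1\\]", "]", nm)
    theta2[nm] <- theta1[nm1]
  }
  expect_equal(log_posterior(s1, d, theta1), log_posterior(s2, d, theta2),
               tolerance = 1e-10)
})

test_that("block models refuse data with unmodelled blocks", {
  d <- mini_trials(blocks = 1:3)
  spec <- spec_block_threshold(d, blocks = 1:2)
  theta <- reference_theta(spec)
  expect_error(log_posterior(spec, d, theta), class = "rrddm_spec_error")
})

test_that("the offset models restrict the likelihood to their block window", {
  d <- mini_trials(n_per_block = 4, blocks = c(2L, 11L, 12L))
  d1 <- d[d$participant_id == "p1", ]
  spec <- spec_optimality_offset(d1, blocks = 11:12)
  theta <- reference_theta(spec)
  lp_all <- log_posterior(spec, d1, theta)
  lp_window <- log_posterior(spec, d1[d1$block >= 11, ], theta)
  expect_identical(lp_all, lp_window)
})

test_that("model specs serialise to JSON", {
  spec <- spec_block_threshold(two_participants(), blocks = 1:2)
  js <- jsonlite::fromJSON(spec_to_json(spec))
  expect_identical(js$model_id, "block_threshold")
  expect_identical(nrow(js$parameters), n_free_parameters(spec))
})
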