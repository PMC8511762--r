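# First-passage density, closed forms, simulator and likelihood of the
# simple diffusion model.

test_that("parameter validation rejects out-of-domain values", {
  expect_error(ddm_params(v = 1, a = 0), class = "rrddm_param_error")
  expect_error(ddm_params(v = 1, a = 1, zr = 1), class = "rrddm_param_error")
  expect_error(ddm_params(v = 1, a = 1, ter = -0.1), class = "rrddm_param_error")
  expect_error(ddm_params(v = 1, a = 1, s = 0), class = "rrddm_param_error")
  expect_s3_class(ddm_params(v = -2, a = 0.5, zr = 0.3, ter = 0.2, s = 0.1),
                  "ddm_params")
})

test_that("density vanishes for non-positive times", {
  p <- ddm_params(v = 2, a = 1.5)
  expect_equal(fpt_density(c(-0.1, 0), p, "upper"), c(0, 0))
  expect_equal(fpt_density(-0.1, p, "lower"), 0)
})

test_that("upper and lower densities integrate to 1 across the parameter grid", {
  for (v in c(-3, -1.5, 0.01, 1.5, 3)) {
    for (a in c(0.5, 1.5, 3)) {
      for (zr in c(0.3, 0.5, 0.7)) {
        p <- ddm_params(v = v, a = a, zr = zr)
        total <- integrate(function(t) {
          fpt_density(t, p, "upper") + fpt_density(t, p, "lower")
        }, 0, 60, subdivisions = 2000L, rel.tol = 1e-8)$value
        expect_lt(abs(total - 1), 1e-4)
      }
    }
  }
})

test_that("integrated upper-boundary mass equals the choice probability", {
  for (v in c(-2, 0.5, 2)) {
    for (zr in c(0.3, 0.5, 0.7)) {
      p <- ddm_params(v = v, a = 1.2, zr = zr)
      mass <- integrate(function(t) fpt_density(t, p, "upper"),
                        0, 60, subdivisions = 2000L, rel.tol = 1e-8)$value
      expect_lt(abs(mass - choice_probability(p)), 1e-4)
    }
  }
})

test_that("reflection symmetry: (v, zr, upper) equals (-v, 1 - zr, lower)", {
  t <- c(0.05, 0.2, 0.5, 1, 3)
  for (v in c(-1.5, 0.7)) {
    for (zr in c(0.35, 0.6)) {
      a <- ddm_params(v = v, a = 1.4, zr = zr)
      b <- ddm_params(v = -v, a = 1.4, zr = 1 - zr)
      expect_equal(fpt_density(t, a, "upper"), fpt_density(t, b, "lower"),
                   tolerance = 1e-12)
      expect_equal(choice_probability(a), 1 - choice_probability(b),
                   tolerance = 1e-10)
      expect_equal(mean_decision_time(a), mean_decision_time(b),
                   tolerance = 1e-10)
    }
  }
})

test_that("choice probability matches its analytic special cases", {
  expect_equal(choice_probability(ddm_params(v = 0, a = 1, zr = 0.4)), 0.4)
  # zr = 0.5 and v a / s^2 = ln 3 gives 1 / (1 + exp(-ln 3)) = 0.75
  expect_equal(choice_probability(ddm_params(v = log(3), a = 1, zr = 0.5)),
               0.75, tolerance = 1e-12)
})

test_that("mean decision time matches the closed forms", {
  # zero-drift limit a^2 / (4 s^2)
  expect_equal(mean_decision_time(ddm_params(v = 1e-12, a = 2, zr = 0.5)),
               1, tolerance = 1e-6)
  expect_equal(mean_decision_time(ddm_params(v = 1, a = 1, zr = 0.5)),
               0.5 * tanh(0.5), tolerance = 1e-10)
})

test_that("simulated trials match the closed-form accuracy and mean RT", {
  p <- ddm_params(v = 2, a = 1.5, zr = 0.5, ter = 0.3)
  n <- 2e5
  sim <- simulate_trials(p, n, seed = 42)
  p_true <- choice_probability(p)
  se_acc <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(sim$response) - p_true), 3 * se_acc)
  mrt_true <- mean_decision_time(p) + p$ter
  se_rt <- sd(sim$rt) / sqrt(n)
  expect_lt(abs(mean(sim$rt) - mrt_true), 3 * se_rt)
})

test_that("simulated first-passage times match the density-implied CDF", {
  p <- ddm_params(v = 1, a = 1, zr = 0.5)
  n <- 2e5
  sim <- simulate_trials(p, n, seed = 9)
  # unconditional decision-time CDF from the density (trapezoidal quadrature)
  h <- 0.002
  grid <- seq(0, 8, by = h)
  dens <- fpt_density(grid, p, "upper") + fpt_density(grid, p, "lower")
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2) * h)
  emp <- ecdf(sim$rt)(grid)
  ks <- max(abs(emp - cdf))
  expect_lt(ks, 0.005)
})

test_that("simulation is deterministic given a seed and n = 0 works", {
  p <- ddm_params(v = 1.5, a = 1, ter = 0.2)
  expect_identical(simulate_trials(p, 50, seed = 3),
                   simulate_trials(p, 50, seed = 3))
  empty <- simulate_trials(p, 0)
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("rt", "response"))
})

test_that("plain Euler simulation runs and carries upward RT bias", {
  p <- ddm_params(v = 2, a = 1.5, zr = 0.5, ter = 0)
  sim <- simulate_trials(p, 2e4, method = "euler", seed = 5)
  # documented discretisation bias: mean RT above the closed form
  expect_gt(mean(sim$rt), mean_decision_time(p))
})

test_that("log likelihood equals the sum of elementwise log densities", {
  p <- ddm_params(v = 1.2, a = 1.3, zr = 0.45, ter = 0.25)
  sim <- simulate_trials(p, 50, seed = 8)
  byhand <- sum(log(ifelse(
    sim$response == 1,
    fpt_density(sim$rt - p$ter, p, "upper"),
    fpt_density(sim$rt - p$ter, p, "lower")
  )))
  expect_equal(ddm_log_likelihood(sim, p), byhand, tolerance = 1e-10)
})

test_that("log likelihood floors impossible trials and is 0 on empty input", {
  p <- ddm_params(v = 1, a = 1, ter = 0.5)
  expect_identical(ddm_log_likelihood(tibble::tibble(rt = numeric(),
                                                     response = integer()),
                                      p), 0)
  # rt below ter: floor engaged, one trial contributes log(1e-10)
  one <- tibble::tibble(rt = 0.3, response = 1L)
  expect_equal(ddm_log_likelihood(one, p), log(1e-10))
  expect_error(ddm_log_likelihood(tibble::tibble(rt = 0.5, response = 2L), p),
               class = "rrddm_input_error")
})

test_that("log likelihood is continuous in each parameter at interior points", {
  sim <- simulate_trials(ddm_params(v = 1.5, a = 1.2, ter = 0.2), 40, seed = 12)
  base <- list(v = 1.5, a = 1.2, zr = 0.5, ter = 0.1, s = 1)
  ll <- function(pl) ddm_log_likelihood(sim, do.call(ddm_params, pl))
  h <- 1e-6
  for (nm in c("v", "a", "zr", "ter")) {
    up <- base; up[[nm]] <- up[[nm]] + h
    dn <- base; dn[[nm]] <- dn[[nm]] - h
    expect_lt(abs(ll(up) - ll(dn)), 1e-2)
  }
})
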