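#' Trial timing constants
#'
#' The reward-rate denominator needs the fixed per-trial time beyond the
#' decision itself: inter-trial interval plus feedback display, lumped into a
#' single `overhead` constant in seconds. The default of 1.0 s is a
#' configurable placeholder — tasks of this kind rarely publish their exact
#' trial bookkeeping — and every Bayes-factor report records the timing used.
#'
#' @param overhead Per-trial overhead in seconds, non-negative.
#' @return A `trial_timing` object.
#' @export
trial_timing <- function(overhead = 1.0) {
  if (!is.numeric(overhead) || length(overhead) != 1 || !is.finite(overhead) ||
      overhead < 0) {
    abort("`overhead` must be a single non-negative number",
          class = "rrddm_config_error")
  }
  structure(list(overhead = overhead), class = "trial_timing")
}

#' Reward rate of a threshold setting
#'
#' Expected correct responses ("points") per second:
#' `P(correct) / (mean decision time + ter + overhead)`, using the diffusion
#' closed forms at an unbiased start (`zr = 0.5`).
#'
#' @param a Boundary separation(s), positive.
#' @param v Drift rate, strictly positive (the objective is undefined without
#'   signal).
#' @param ter Non-decision time in seconds.
#' @param timing A [trial_timing()] object.
#' @param s Diffusion coefficient.
#' @return Reward rate(s) in points per second.
#' @examples
#' reward_rate(a = 1, v = 1, ter = 0.3, timing = trial_timing(1))
#' @export
reward_rate <- function(a, v, ter, timing = trial_timing(), s = 1) {
  stopifnot(inherits(timing, "trial_timing"))
  if (any(v <= 0)) {
    abort("reward rate requires drift rate v > 0", class = "rrddm_param_error")
  }
  if (any(a <= 0) || any(ter < 0)) {
    abort("need a > 0 and ter >= 0", class = "rrddm_param_error")
  }
  x <- v * a / s^2
  p <- 1 / (1 + exp(-x))
  dt <- (a / (2 * v)) * tanh(x / 2)
  p / (dt + ter + timing$overhead)
}

#' Reward-rate-optimal decision threshold
#'
#' The boundary separation `a*` maximising [reward_rate()] over
#' `(1e-6, a_max]`, found by a coarse global scan followed by golden-section
#' refinement to tolerance `tol`. As total dead time (`ter + overhead`) goes
#' to zero the optimum collapses to zero (instant guessing); `a*` is
#' non-decreasing in overhead.
#'
#' @param v Drift rate(s), strictly positive (vectorised with `ter`).
#' @param ter Non-decision time(s) in seconds.
#' @inheritParams reward_rate
#' @param a_max Upper search bound.
#' @param tol Bracket tolerance of the optimiser.
#' @return Optimal threshold(s) `a*`.
#' @examples
#' optimal_threshold(v = 1, ter = 0.3, timing = trial_timing(1))
#' @export
optimal_threshold <- function(v, ter, timing = trial_timing(), s = 1,
                              a_max = 10, tol = 1e-6) {
  stopifnot(inherits(timing, "trial_timing"))
  if (any(v <= 0) || anyNA(v)) {
    abort("optimal threshold requires drift rate v > 0",
          class = "rrddm_param_error")
  }
  n <- max(length(v), length(ter))
  v <- rep_len(as.numeric(v), n)
  ter <- rep_len(as.numeric(ter), n)
  if (any(ter < 0)) abort("ter must be >= 0", class = "rrddm_param_error")
  optimal_threshold_cpp(v, ter, timing$overhead, s, a_max, tol)
}

#' Posterior predictive distribution of the optimal threshold
#'
#' Maps [optimal_threshold()] over posterior draws of drift rate and
#' non-decision time and summarises the implied `a*` distribution with the
#' quantile bands used to display optimality regions (0.2/0.4/0.6/0.8
#' quantiles plus 95% tails). Draws with non-positive drift cannot define an
#' optimum; they are excluded and counted.
#'
#' @param draws A data frame with numeric columns `v` and `ter`, one row per
#'   posterior draw (an optional `entity` column keeps per-participant or
#'   per-group draws separate).
#' @inheritParams optimal_threshold
#' @return An `optimal_threshold_posterior`: list with `samples` (tibble of
#'   the input draws plus `a_star`), `summary` (tibble of quantiles per
#'   entity) and `n_excluded`.
#' @export
posterior_predictive_optimal <- function(draws, timing = trial_timing(),
                                         s = 1) {
  if (!is.data.frame(draws) || !all(c("v", "ter") %in% names(draws))) {
    abort("`draws` needs columns v and ter", class = "rrddm_input_error")
  }
  draws <- tibble::as_tibble(draws)
  if (!"entity" %in% names(draws)) draws$entity <- "all"
  bad <- !is.finite(draws$v) | draws$v <= 0 | !is.finite(draws$ter)
  n_excluded <- sum(bad)
  kept <- draws[!bad, , drop = FALSE]
  kept$a_star <- optimal_threshold(kept$v, kept$ter, timing = timing, s = s)
  summary <- kept |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(
      opt_q02 = unname(quantile(.data$a_star, 0.2)),
      opt_q04 = unname(quantile(.data$a_star, 0.4)),
      opt_median = unname(median(.data$a_star)),
      opt_q06 = unname(quantile(.data$a_star, 0.6)),
      opt_q08 = unname(quantile(.data$a_star, 0.8)),
      opt_tail_low = unname(quantile(.data$a_star, 0.025)),
      opt_tail_high = unname(quantile(.data$a_star, 0.975)),
      .groups = "drop"
    )
  structure(
    list(samples = kept, summary = summary, n_excluded = n_excluded,
         timing = timing),
    class = "optimal_threshold_posterior"
  )
}

#' @export
print.optimal_threshold_posterior <- function(x, ...) {
  cat("<optimal_threshold_posterior>",
      nrow(x$samples), "draws,", x$n_excluded, "excluded\n")
  print(x$summary)
  invisible(x)
}

#' Block-threshold versus optimal-threshold comparison table
#'
#' The qualitative optimality display: per block, the posterior median and
#' 95% credible interval of the group-level block threshold, alongside the
#' quantile bands of the posterior predictive optimal-threshold
#' distribution for that group. Thresholds come from a fitted
#' block-threshold model; the optimal band maps `a*` over posterior
#' predictive draws of (v, ter) from the group-level hyperparameters.
#'
#' @param fit A `ddm_fit` of model `block_threshold` or
#'   `block_threshold_drift`.
#' @inheritParams optimal_threshold
#' @param seed Seed for the posterior predictive (v, ter) draws.
#' @return A tibble with one row per (group, block): `median`, `ci_low`,
#'   `ci_high` for the threshold and `opt_*` band columns.
#' @export
threshold_optimality_table <- function(fit, timing = trial_timing(), s = NULL,
                                       seed = 1) {
  stopifnot(inherits(fit, "ddm_fit"))
  spec <- fit$spec
  if (!spec$model_id %in% c("block_threshold", "block_threshold_drift")) {
    abort("threshold_optimality_table needs a block-threshold model fit",
          class = "rrddm_spec_error")
  }
  s <- s %||% spec$s
  draws <- posterior_matrix(fit$samples)  # pooled draws x parameters
  pr <- spec$pars
  out <- list()
  withr::with_seed(seed, {
    for (g in spec$groups) {
      mu_a <- pr$name[pr$role == "hyper" & pr$group == g & pr$param == "mu_a"]
      if (!length(mu_a)) {
        abort("no block-threshold hyperparameters found for group ", g,
              class = "rrddm_spec_error")
      }
      blocks <- pr$block[match(mu_a, pr$name)]
      thr <- tibble::tibble(
        group = g,
        block = blocks,
        median = unname(apply(draws[, mu_a, drop = FALSE], 2, median)),
        ci_low = unname(apply(draws[, mu_a, drop = FALSE], 2, quantile, 0.025)),
        ci_high = unname(apply(draws[, mu_a, drop = FALSE], 2, quantile, 0.975))
      )
      # posterior predictive (v, ter): one new participant per draw
      vb <- pr[pr$role == "individual" & pr$param == "v", ][1, ]
      tb <- pr[pr$role == "individual" & pr$param == "ter", ][1, ]
      nd <- nrow(draws)
      # under the block-drift robustness model, drift hyperparameters are
      # per block; average them for the predictive draw
      vm <- paste0("mu_v[", g, "]")
      vs <- paste0("sigma_v[", g, "]")
      if (!vm %in% colnames(draws)) {
        vcols <- pr$name[pr$role == "hyper" & pr$group == g & pr$param == "mu_v"]
        scols <- pr$name[pr$role == "hyper" & pr$group == g & pr$param == "sigma_v"]
        mu_v_draws <- rowMeans(draws[, vcols, drop = FALSE])
        sd_v_draws <- rowMeans(draws[, scols, drop = FALSE])
      } else {
        mu_v_draws <- draws[, vm]
        sd_v_draws <- draws[, vs]
      }
      vpred <- rtnorm(nd, mu_v_draws, sd_v_draws, vb$lower, vb$upper)
      tpred <- rtnorm(nd, draws[, paste0("mu_ter[", g, "]")],
                      draws[, paste0("sigma_ter[", g, "]")], tb$lower, tb$upper)
      opt <- posterior_predictive_optimal(
        tibble::tibble(v = vpred, ter = tpred, entity = g),
        timing = timing, s = s
      )
      out[[g]] <- dplyr::cross_join(thr, dplyr::select(opt$summary, -"entity"))
    }
  })
  res <- dplyr::bind_rows(out)
  attr(res, "timing") <- timing
  class(res) <- c("rrddm_threshold_table", class(res))
  res
}
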