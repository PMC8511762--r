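#' Savage-Dickey Bayes factor at a point null
#'
#' For a parameter with a prior nested at 0, the Bayes factor against the
#' point null is the ratio of prior to posterior density at 0. The posterior
#' density is estimated by Gaussian kernel density with Silverman's
#' bandwidth on the pooled post-burn-in draws (a normal-approximation
#' estimator is available as `estimator = "normal"`; the result records
#' which was used). A vanishing density estimate is floored at 1e-12 and the
#' BF flagged as a lower bound.
#'
#' @param draws Pooled posterior draws of the tested parameter (>= 500).
#' @param prior_density_at_zero Prior density evaluated at 0 (finite,
#'   positive).
#' @param parameter Label for the tested parameter.
#' @param hypothesis Label for the hypothesis.
#' @param estimator `"kde"` (Gaussian kernel, Silverman bandwidth) or
#'   `"normal"` (moment-matched normal).
#' @return A one-row `bf_result` tibble: densities at 0, `bf10`
#'   (= prior / posterior at 0, evidence against the null), `bf01`,
#'   `direction` (posterior mass above 0), bandwidth, estimator, and a
#'   lower-bound flag.
#' @examples
#' savage_dickey(rnorm(2000, 1, 0.3), prior_density_at_zero = dnorm(0))
#' @export
savage_dickey <- function(draws, prior_density_at_zero,
                          parameter = "theta", hypothesis = NA_character_,
                          estimator = c("kde", "normal")) {
  estimator <- match.arg(estimator)
  draws <- as.numeric(draws)
  if (length(draws) < 500) {
    abort("Savage-Dickey estimation needs at least 500 posterior draws",
          class = "rrddm_input_error")
  }
  if (!is.finite(prior_density_at_zero) || prior_density_at_zero <= 0) {
    abort("prior density at 0 must be finite and positive",
          class = "rrddm_input_error")
  }
  if (estimator == "kde") {
    bw <- stats::bw.nrd0(draws)
    post0 <- mean(dnorm(0, mean = draws, sd = bw))
  } else {
    bw <- NA_real_
    post0 <- dnorm(0, mean = mean(draws), sd = sd(draws))
  }
  floored <- post0 < 1e-12
  post0 <- max(post0, 1e-12)
  tibble::new_tibble(
    tibble::tibble(
      hypothesis = hypothesis,
      parameter = parameter,
      prior_density_0 = prior_density_at_zero,
      posterior_density_0 = post0,
      bf10 = prior_density_at_zero / post0,
      bf01 = post0 / prior_density_at_zero,
      direction = mean(draws > 0),
      n_draws = length(draws),
      bandwidth = bw,
      estimator = estimator,
      bf_is_lower_bound = floored
    ),
    class = "bf_result"
  )
}

#' Test each group's deviation from optimality
#'
#' Applies the Savage-Dickey ratio to the posterior draws of the group-level
#' distance-from-optimality mean `mu_c` of each group's fitted
#' optimality-offset model. Under the additive-offset convention, posterior
#' mass of `mu_c` above 0 (`direction` near 1) reads as the group being too
#' cautious.
#'
#' @param fits Named list of `ddm_fit` objects of model `optimality_offset`,
#'   one per group.
#' @inheritParams savage_dickey
#' @return A `bf_result` tibble with one row per group.
#' @export
bf_optimality_offset <- function(fits, estimator = c("kde", "normal")) {
  estimator <- match.arg(estimator)
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "ddm_fit"))) {
    abort("`fits` must be a named list of ddm_fit objects",
          class = "rrddm_order_error")
  }
  rows <- purrr::imap(fits, function(fit, g) {
    if (fit$spec$model_id != "optimality_offset") {
      abort("bf_optimality_offset needs optimality_offset fits",
            class = "rrddm_order_error")
    }
    prior <- fit$spec$priors$mu_c
    res <- savage_dickey(parameter_draws(fit, "mu_c"),
                         dnorm(0, prior[1], prior[2]),
                         parameter = "mu_c",
                         hypothesis = "deviation_from_optimality",
                         estimator = estimator)
    res$group <- g
    res$timing_overhead <- fit$spec$timing$overhead
    res
  })
  dplyr::bind_rows(rows)
}

#' Test the group difference in distance from optimality
#'
#' Savage-Dickey ratio on `delta_c = mu_c[fixed_time] - mu_c[fixed_trial]`
#' from a fitted group-difference model; `direction` is the posterior mass
#' of `delta_c` above 0, i.e. the fixed-time group sitting further above
#' optimality than the fixed-trial group.
#'
#' @param fit A `ddm_fit` of model `group_difference`.
#' @inheritParams savage_dickey
#' @return A one-row `bf_result` tibble.
#' @export
bf_group_difference <- function(fit, estimator = c("kde", "normal")) {
  estimator <- match.arg(estimator)
  if (!inherits(fit, "ddm_fit") || fit$spec$model_id != "group_difference") {
    abort("bf_group_difference needs a group_difference fit",
          class = "rrddm_order_error")
  }
  prior <- fit$spec$priors$delta_c
  res <- savage_dickey(parameter_draws(fit, "delta_c"),
                       dnorm(0, prior[1], prior[2]),
                       parameter = "delta_c",
                       hypothesis = "group_difference",
                       estimator = estimator)
  res$timing_overhead <- fit$spec$timing$overhead
  res
}

#' Qualitative approach-to-optimality trend
#'
#' Summarises a [threshold_optimality_table()] per block: the absolute
#' distance between the threshold posterior median and the optimal-threshold
#' median, whether the threshold's 95% credible interval overlaps the
#' 0.2-0.8 optimal band, and a descriptive Kendall's tau of distance against
#' block index (negative tau: thresholds approach optimality over blocks).
#' The trend is explicitly qualitative; no Bayes factor is attached.
#'
#' @param table Output of [threshold_optimality_table()].
#' @return An `optimality_trend`: list with the per-block tibble and a
#'   per-group tibble of tau values (`NA` with a single block).
#' @export
optimality_trend <- function(table) {
  need <- c("group", "block", "median", "ci_low", "ci_high",
            "opt_median", "opt_q02", "opt_q08")
  if (!all(need %in% names(table))) {
    abort("`table` must come from threshold_optimality_table()",
          class = "rrddm_input_error")
  }
  per_block <- table |>
    dplyr::mutate(
      distance = abs(.data$median - .data$opt_median),
      overlaps_band = .data$ci_low <= .data$opt_q08 &
        .data$ci_high >= .data$opt_q02
    )
  trend <- per_block |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      kendall_tau = if (dplyr::n() < 2) NA_real_ else
        suppressWarnings(cor(.data$distance, .data$block,
                             method = "kendall")),
      n_blocks = dplyr::n(),
      .groups = "drop"
    )
  structure(list(per_block = per_block, trend = trend, qualitative = TRUE),
            class = "optimality_trend")
}

#' @export
print.optimality_trend <- function(x, ...) {
  cat("<optimality_trend> (qualitative summary)\n")
  print(x$trend)
  invisible(x)
}
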