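#' Simple diffusion model parameters
#'
#' Bundles and validates the parameter vector of the simple (no between-trial
#' variability) diffusion decision model: drift rate `v`, boundary separation
#' `a`, relative starting point `zr` (absolute start `z = zr * a`), non-decision
#' time `ter`, and diffusion coefficient `s`.
#'
#' The diffusion coefficient is a scaling convention, not a free parameter:
#' `s = 1` by default, with `s = 0.1` selectable for compatibility with
#' fast-dm-scaled parameter values.
#'
#' @param v Drift rate (evidence units per second); positive values drive the
#'   process toward the upper (correct) boundary.
#' @param a Boundary separation (evidence units), must be positive.
#' @param zr Relative starting point in (0, 1); 0.5 is unbiased.
#' @param ter Non-decision time in seconds, non-negative.
#' @param s Diffusion coefficient (evidence units per sqrt-second), positive.
#' @return A `ddm_params` object (named list).
#' @examples
#' p <- ddm_params(v = 2, a = 1.5)
#' choice_probability(p)
#' @export
ddm_params <- function(v, a, zr = 0.5, ter = 0, s = 1) {
  ok <- is.numeric(v) && is.finite(v) &&
    is.numeric(a) && is.finite(a) && a > 0 &&
    is.numeric(zr) && is.finite(zr) && zr > 0 && zr < 1 &&
    is.numeric(ter) && is.finite(ter) && ter >= 0 &&
    is.numeric(s) && is.finite(s) && s > 0
  if (!ok) {
    abort(
      "invalid diffusion parameters: need finite v; a > 0; 0 < zr < 1; ter >= 0; s > 0",
      class = "rrddm_param_error"
    )
  }
  structure(list(v = v, a = a, zr = zr, ter = ter, s = s),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "<ddm_params> v = %.4g, a = %.4g, zr = %.4g, ter = %.4g, s = %.4g\n",
    x$v, x$a, x$zr, x$ter, x$s
  ))
  invisible(x)
}

as_ddm_params <- function(p) {
  if (inherits(p, "ddm_params")) return(p)
  ddm_params(p$v, p$a, p$zr %||% 0.5, p$ter %||% 0, p$s %||% 1)
}

#' First-passage-time density of the simple diffusion model
#'
#' Density of the decision time (response time minus non-decision time) at one
#' boundary, via the small-time / large-time series representations with the
#' truncation chosen per evaluation to keep the absolute error below `err`.
#' Non-positive times have density zero.
#'
#' @param t Decision times in seconds (vectorised).
#' @param params A [ddm_params()] object.
#' @param boundary `"upper"` (correct) or `"lower"` (error).
#' @param err Absolute series-truncation error bound.
#' @return Densities (1/s), same length as `t`.
#' @examples
#' fpt_density(c(0.2, 0.5, 1), ddm_params(v = 2, a = 1.5))
#' @export
fpt_density <- function(t, params, boundary = c("upper", "lower"),
                        err = 1e-7) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  fpt_density_cpp(as.numeric(t), params$v, params$a, params$zr, params$s,
                  boundary == "upper", err)
}

#' Probability of an upper-boundary (correct) response
#'
#' Closed form `(1 - exp(-2 v zr a / s^2)) / (1 - exp(-2 v a / s^2))`, with the
#' continuous limit `zr` at `v = 0`.
#'
#' @inheritParams fpt_density
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(params) {
  params <- as_ddm_params(params)
  k <- 2 * params$v * params$a / params$s^2
  if (abs(k) < 1e-9) return(params$zr)
  expm1(-k * params$zr) / expm1(-k)
}

#' Mean decision time of the simple diffusion model
#'
#' Mean first-passage time across both boundaries, excluding non-decision
#' time. For an unbiased start this is `(a / 2v) tanh(v a / 2 s^2)`; the
#' general form follows the standard two-boundary exit-time formula, with the
#' zero-drift limit `z (a - z) / s^2`.
#'
#' @inheritParams fpt_density
#' @return Mean decision time in seconds.
#' @export
mean_decision_time <- function(params) {
  params <- as_ddm_params(params)
  z <- params$zr * params$a
  s2 <- params$s^2
  if (abs(params$v * params$a / s2) < 1e-7) {
    return(z * (params$a - z) / s2)
  }
  p_up <- choice_probability(params)
  params$a * p_up / params$v - z / params$v
}

#' Simulate diffusion-model trials
#'
#' Path simulation by Euler-Maruyama with step `dt`. The default `"bridge"`
#' method additionally applies the exact Brownian-bridge within-step
#' boundary-crossing test (exact for constant drift and diffusion), removing
#' the order-sqrt(dt) missed-crossing bias of the plain scheme; `"euler"`
#' gives the uncorrected scheme and carries that documented discretisation
#' bias.
#'
#' @inheritParams fpt_density
#' @param n Number of trials (non-negative).
#' @param dt Time step in seconds.
#' @param method `"bridge"` (default) or `"euler"`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   trials exactly.
#' @return A tibble with columns `rt` (seconds, includes `ter`) and
#'   `response` (1 = upper/correct, 0 = lower/error).
#' @examples
#' simulate_trials(ddm_params(v = 2, a = 1.5, ter = 0.3), n = 5, seed = 1)
#' @export
simulate_trials <- function(params, n, dt = 0.001,
                            method = c("bridge", "euler"), seed = NULL) {
  params <- as_ddm_params(params)
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer", class = "rrddm_input_error")
  }
  run <- function() {
    sim <- simulate_ddm_cpp(as.integer(n), params$v, params$a, params$zr,
                            params$ter, params$s, dt, method == "bridge",
                            t_max = 300)
    tibble::tibble(rt = sim$rt, response = as.integer(sim$response))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Diffusion-model log likelihood of a trial set
#'
#' Sum of log first-passage densities at `rt - ter`, upper boundary for
#' correct responses and lower for errors. Densities are floored at `floor`
#' before logging, so an impossible trial (e.g. `rt < ter`) contributes a
#' large finite penalty rather than `-Inf`; this keeps DE-MCMC proposals
#' comparable.
#'
#' @param trials A data frame with numeric `rt` (> 0, seconds) and `response`
#'   in {0, 1}.
#' @inheritParams fpt_density
#' @param floor Density floor.
#' @return A single log-likelihood value; 0 for an empty trial set.
#' @export
ddm_log_likelihood <- function(trials, params, floor = 1e-10, err = 1e-7) {
  params <- as_ddm_params(params)
  check_trial_columns(trials, c("rt", "response"))
  n <- nrow(trials)
  if (n == 0) return(0)
  ddm_loglik_cpp(as.numeric(trials$rt), as.integer(trials$response),
                 rep(params$v, n), rep(params$a, n),
                 params$zr, params$ter, params$s, floor, err)
}

check_trial_columns <- function(trials, cols) {
  if (!is.data.frame(trials)) {
    abort("`trials` must be a data frame", class = "rrddm_input_error")
  }
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    abort(paste0("`trials` is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rrddm_input_error")
  }
  if ("rt" %in% cols && (!is.numeric(trials$rt) || anyNA(trials$rt))) {
    abort("column `rt` must be numeric and non-missing",
          class = "rrddm_input_error")
  }
  if ("response" %in% cols &&
      (anyNA(trials$response) || !all(trials$response %in% c(0, 1)))) {
    abort("column `response` must be 0 or 1", class = "rrddm_input_error")
  }
  invisible(trials)
}
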