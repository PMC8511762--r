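#' Render a preregistration skeleton
#'
#' Emits a markdown analysis-plan skeleton with the four structured
#' sections of a model-application preregistration: A (cognitive model and
#' parameterisation, auto-filled with the selected model's full parameter
#' inventory and priors), B (method of parameter estimation: chains,
#' iterations, burn-in, migration), C (robustness checks and parameter
#' recovery design), and D (contingency plans). Anything the configuration
#' does not determine is rendered as an explicit `TODO` prompt, never
#' silently omitted.
#'
#' @param spec A `ddm_model_spec` describing the estimation model.
#' @param sampler A [de_config()].
#' @param robustness Character vector describing configured robustness
#'   checks (empty: rendered as a TODO).
#' @param recovery_design Optional [experiment_design()] used for parameter
#'   recovery.
#' @param contingencies Character vector of contingency plans (empty:
#'   rendered as a TODO).
#' @return The document as a single character string (markdown).
#' @examples
#' spec <- spec_block_threshold(
#'   tibble::tibble(participant_id = c("p1", "p2"),
#'                  group = "fixed_time"), blocks = 1:3)
#' cat(substr(render_prereg(spec), 1, 300))
#' @export
render_prereg <- function(spec, sampler = de_config(),
                          robustness = c(
                            "(a) replicate the key analysis including initially excluded trials and participants",
                            "(b) replicate the key analysis with a model in which threshold and drift rate vary across blocks"
                          ),
                          recovery_design = NULL,
                          contingencies = character()) {
  stopifnot(inherits(spec, "ddm_model_spec"), inherits(sampler, "de_config"))
  fmt_prior <- function(loc, scale, lo, hi) {
    if (is.infinite(lo) && is.infinite(hi)) {
      sprintf("Normal(%g, %g)", loc, scale)
    } else {
      sprintf("TruncNormal(%g, %g, [%g, %g])", loc, scale, lo, hi)
    }
  }
  pars <- spec$pars
  inv <- vapply(seq_len(nrow(pars)), function(i) {
    p <- pars[i, ]
    if (p$role == "hyper") {
      sprintf("- `%s` (group level): %s", p$name,
              fmt_prior(p$prior_loc, p$prior_scale, p$prior_lower,
                        p$prior_upper))
    } else {
      sprintf("- `%s` (individual): ~ TruncNormal(`%s`, `%s`, [%g, %g])",
              p$name, p$hyper_loc %|NA|% "mu_c_bar +/- delta_c/2",
              p$hyper_scale, p$lower, p$upper)
    }
  }, character(1))
  todo <- function(x, prompt) {
    if (length(x) && any(nzchar(x))) paste0("- ", x) else
      paste0("- TODO: ", prompt)
  }
  lines <- c(
    "# Preregistered analysis plan (skeleton)",
    "",
    "## A. Cognitive model",
    "",
    sprintf("Simple diffusion model (drift rate v, threshold a, relative starting point zr, non-decision time ter; diffusion coefficient s = %g fixed), estimated with Bayesian hierarchical modelling; individual-level parameters follow group-level truncated normal distributions and the groups have separate hierarchies.", spec$s),
    "",
    sprintf("Model structure: `%s`; %d participants in %d group(s)%s.",
            spec$model_id, nrow(spec$participants), length(spec$groups),
            if (!is.null(spec$blocks))
              sprintf("; modelled blocks %s",
                      paste(range(spec$blocks), collapse = "-")) else ""),
    "",
    sprintf("Free parameters (%d):", nrow(pars)),
    inv,
    "",
    "## B. Method of parameter estimation",
    "",
    sprintf("- Markov chain Monte Carlo with differential-evolution proposals: %d chains, %d samples per chain, first %d discarded as burn-in.",
            sampler$n_chains, sampler$n_iter, sampler$burn_in),
    sprintf("- Migration step with per-iteration probability %g to assist convergence.",
            sampler$migration_prob),
    sprintf("- Proposal scale gamma = %s with uniform jitter of half-width %g; %g%% of proposals use gamma = 1.",
            if (is.null(sampler$gamma)) "2.38 / sqrt(2 d)" else
              format(sampler$gamma),
            sampler$jitter, 100 * sampler$gamma1_prob),
    "- Chain starts drawn from the priors until the log posterior is finite.",
    "",
    "## C. Robustness checks and sensitivity analyses",
    "",
    todo(robustness, "specify planned robustness checks and sensitivity analyses"),
    "",
    if (!is.null(recovery_design)) {
      sprintf("Parameter recovery design: %d participants per group, %d blocks (fixed-trial blocks of %d trials; fixed-time blocks of %g s).",
              recovery_design$n_per_group, recovery_design$n_blocks,
              recovery_design$fixed_trials, recovery_design$fixed_time)
    } else {
      "- TODO: report the parameter recovery study design and results"
    },
    "",
    "## D. Contingency plans",
    "",
    todo(contingencies, "specify contingency plans (poor fit, sampler non-convergence, compute budget)"),
    ""
  )
  paste(lines, collapse = "\n")
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x
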