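#' Parameter-recovery study
#'
#' The preregistered substitute for a power analysis: generate synthetic
#' datasets from known parameters, preprocess and refit with the same model,
#' and compare generating values with recovered posterior medians. Reports
#' Pearson correlation, mean signed bias and RMSE per parameter type; no
#' fixed pass/fail threshold is imposed.
#'
#' @param design An [experiment_design()].
#' @param populations Named list of [group_population()]s (groups
#'   `fixed_time`, `fixed_trial`).
#' @param model Model id to fit (see [fit_ddm()]).
#' @param config A [de_config()] for the refits.
#' @param n_replicates Number of generate-and-refit replicates.
#' @param seed Root seed; replicate r uses `seed + r` for generation and
#'   fitting.
#' @param exclusions An [exclusion_config()] applied before refitting.
#' @return A `recovery_report`: `$stats` (per-parameter tibble),
#'   `$pairs` (generating vs recovered values), `$replicates`
#'   (per-replicate convergence), `$design`, `$seed`.
#' @export
run_recovery <- function(design, populations = list(
                           fixed_time = group_population(),
                           fixed_trial = group_population()
                         ),
                         model = "block_threshold",
                         config = de_config(), n_replicates = 1, seed = 1,
                         exclusions = exclusion_config()) {
  stopifnot(inherits(design, "experiment_design"))
  pairs <- list(); reps <- list()
  for (r in seq_len(n_replicates)) {
    d <- generate_dataset(design, populations, seed = seed + r)
    truth <- attr(d, "truth")
    dp <- apply_exclusions(d, exclusions)
    fit <- withCallingHandlers(
      fit_ddm(dp, model = model, config = config, seed = seed + r,
              timing = design$timing),
      warning = function(w) invokeRestart("muffleWarning")
    )
    est <- tidy(fit)
    ind <- est[est$role == "individual", , drop = FALSE]
    kept_truth <- truth$participants[
      truth$participants$participant_id %in% dp$participant_id, , drop = FALSE]
    pr <- dplyr::bind_rows(
      # scalar participant parameters
      ind[is.na(ind$block) & ind$param %in% c("v", "zr", "ter"), ] |>
        dplyr::inner_join(
          tidyr::pivot_longer(kept_truth, c("v", "zr", "ter"),
                              names_to = "param",
                              values_to = "generating"),
          by = c(participant = "participant_id", "param"),
          suffix = c("", ".t")
        ) |>
        dplyr::transmute(replicate = r, param = .data$param,
                         participant = .data$participant,
                         generating = .data$generating,
                         recovered = .data$median),
      # per-block thresholds
      ind[ind$param == "a", ] |>
        dplyr::inner_join(
          dplyr::rename(truth$thresholds, participant = "participant_id",
                        generating = "a"),
          by = c("participant", "block")
        ) |>
        dplyr::transmute(replicate = r, param = "a",
                         participant = .data$participant,
                         generating = .data$generating,
                         recovered = .data$median),
      # mean block threshold per participant
      ind[ind$param == "a", ] |>
        dplyr::group_by(.data$participant) |>
        dplyr::summarise(recovered = mean(.data$median), .groups = "drop") |>
        dplyr::inner_join(
          truth$thresholds |>
            dplyr::filter(if (exclusions$drop_first_block) .data$block > 1 else TRUE) |>
            dplyr::group_by(participant = .data$participant_id) |>
            dplyr::summarise(generating = mean(.data$a), .groups = "drop"),
          by = "participant"
        ) |>
        dplyr::mutate(replicate = r, param = "a_mean")
    )
    pairs[[r]] <- pr
    reps[[r]] <- tibble::tibble(
      replicate = r,
      n_participants = length(unique(dp$participant_id)),
      max_rhat = if (is.null(fit$rhat)) NA_real_ else max(fit$rhat$rhat),
      converged = if (is.null(fit$rhat)) NA else max(fit$rhat$rhat) <= 1.1,
      runtime_s = fit$runtime
    )
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(replicate = integer(), param = character(),
                   participant = character(), generating = numeric(),
                   recovered = numeric())
  stats <- recovery_stats(pairs)
  structure(
    list(stats = stats, pairs = pairs,
         replicates = if (length(reps)) dplyr::bind_rows(reps) else
           tibble::tibble(),
         design = design, model = model, seed = seed,
         n_replicates = n_replicates),
    class = "recovery_report"
  )
}

recovery_stats <- function(pairs) {
  if (!nrow(pairs)) {
    return(tibble::tibble(param = character(), n = integer(),
                          correlation = numeric(), bias = numeric(),
                          rmse = numeric()))
  }
  pairs |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(
      n = dplyr::n(),
      correlation = if (dplyr::n() > 2)
        cor(.data$generating, .data$recovered) else NA_real_,
      bias = mean(.data$recovered - .data$generating),
      rmse = sqrt(mean((.data$recovered - .data$generating)^2)),
      .groups = "drop"
    )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> model %s, %d replicate(s)\n",
              x$model, x$n_replicates))
  print(x$stats)
  invisible(x)
}

#' Preregistered robustness checks
#'
#' Reruns the key analyses under the two preregistered variants:
#' (a) `no_exclusions` — the full pipeline with initially excluded trials
#' and participants reinstated; and (b) `block_drift` — the alternative
#' model in which drift rate as well as threshold varies across blocks.
#' Results are labelled as robustness variants and never overwrite the
#' primary analyses.
#'
#' @param data A raw (unpreprocessed) trial table.
#' @param config A [de_config()] for the refits.
#' @param timing A [trial_timing()].
#' @param exclusions The primary [exclusion_config()] (variant (a) replaces
#'   it with [no_exclusions()]).
#' @param priors Prior overrides.
#' @param blocks_bf Blocks entering the Bayes-factor models.
#' @param seed Integer seed shared by all refits.
#' @param include Which analyses to rerun per variant: any of
#'   `"bayes_factors"`, `"threshold_table"`.
#' @return A `robustness_report` with exactly the two variants.
#' @export
run_robustness <- function(data, config = de_config(),
                           timing = trial_timing(),
                           exclusions = exclusion_config(), priors = NULL,
                           blocks_bf = 11:20, seed = 1,
                           include = c("bayes_factors", "threshold_table")) {
  include <- match.arg(include, several.ok = TRUE)
  run_bf <- function(dp) {
    fits <- lapply(
      stats::setNames(nm = sort(unique(dp$group))),
      function(g) suppressWarnings(
        fit_ddm(dp, "optimality_offset", group = g, blocks = blocks_bf,
                config = config, priors = priors, timing = timing,
                seed = seed)
      )
    )
    per_group <- bf_optimality_offset(fits)
    diff <- if (length(fits) == 2) {
      suppressWarnings(
        bf_group_difference(
          fit_ddm(dp, "group_difference", blocks = blocks_bf, config = config,
                  priors = priors, timing = timing, seed = seed)
        )
      )
    } else NULL
    dplyr::bind_rows(per_group, diff)
  }
  variants <- list()

  # (a) exclusion-free preprocessing, primary model structures
  dp_a <- apply_exclusions(data, no_exclusions())
  va <- list(label = "robustness: no exclusions")
  if ("bayes_factors" %in% include) va$bayes_factors <- run_bf(dp_a)
  if ("threshold_table" %in% include) {
    fit_a <- suppressWarnings(
      fit_ddm(dp_a, "block_threshold", config = config, priors = priors,
              timing = timing, seed = seed)
    )
    va$threshold_table <- threshold_optimality_table(fit_a, timing = timing,
                                                     seed = seed)
  }
  variants$no_exclusions <- va

  # (b) block-threshold-and-drift model, primary preprocessing
  dp_b <- apply_exclusions(data, exclusions)
  vb <- list(label = "robustness: threshold and drift vary across blocks")
  fit_b <- suppressWarnings(
    fit_ddm(dp_b, "block_threshold_drift", config = config, priors = priors,
            timing = timing, seed = seed)
  )
  vb$n_parameters <- n_free_parameters(fit_b$spec)
  if ("threshold_table" %in% include) {
    vb$threshold_table <- threshold_optimality_table(fit_b, timing = timing,
                                                     seed = seed)
  }
  variants$block_drift <- vb

  structure(list(variants = variants, seed = seed, include = include),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report> variants:",
      paste(names(x$variants), collapse = ", "), "\n")
  invisible(x)
}
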