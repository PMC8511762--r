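#' Preregistered exclusion configuration
#'
#' The trial- and participant-level exclusion rules, applied in a fixed
#' order: drop the first (practice) block, drop trials with response times
#' below `rt_min` or above `rt_max`, then — on the surviving trials — drop
#' participants with accuracy below `min_accuracy` or fewer than
#' `min_eligible_trials` eligible trials. All thresholds are strict
#' ("below" / "less than"): boundary values are kept.
#'
#' @param drop_first_block Drop block 1 of every participant.
#' @param rt_min,rt_max Response-time window in seconds.
#' @param min_accuracy Minimum fraction correct.
#' @param min_eligible_trials Minimum trials surviving trial-level exclusion.
#' @return An `exclusion_config` object.
#' @export
exclusion_config <- function(drop_first_block = TRUE, rt_min = 0.150,
                             rt_max = 10.0, min_accuracy = 0.60,
                             min_eligible_trials = 200) {
  ok <- rt_min > 0 && rt_min < rt_max && min_accuracy >= 0 &&
    min_accuracy <= 1 && min_eligible_trials >= 0
  if (!ok) {
    abort("invalid exclusion config: need 0 < rt_min < rt_max and 0 <= min_accuracy <= 1",
          class = "rrddm_config_error")
  }
  structure(
    list(drop_first_block = isTRUE(drop_first_block), rt_min = rt_min,
         rt_max = rt_max, min_accuracy = min_accuracy,
         min_eligible_trials = min_eligible_trials),
    class = "exclusion_config"
  )
}

#' No-op exclusion configuration
#'
#' Keeps every trial and participant (used by the robustness re-analysis that
#' reinstates initially excluded data) while still marking the table as
#' preprocessed.
#' @return An `exclusion_config`.
#' @export
no_exclusions <- function() {
  exclusion_config(drop_first_block = FALSE, rt_min = 1e-12, rt_max = Inf,
                   min_accuracy = 0, min_eligible_trials = 0)
}

#' Trial-level exclusions
#'
#' Removes the first block (if configured), then trials with `rt` strictly
#' below `rt_min` or strictly above `rt_max`. The per-rule removal counts are
#' attached as a report fragment; the returned table carries a processed flag
#' that [exclude_participants()] requires.
#'
#' @param table A trial tibble.
#' @param config An [exclusion_config()].
#' @return The kept tibble with attributes `trial_report` and flags.
#' @export
exclude_trials <- function(table, config = exclusion_config()) {
  validate_trial_table(table)
  stopifnot(inherits(config, "exclusion_config"))
  n0 <- nrow(table)
  keep <- rep(TRUE, n0)
  rule <- rep(NA_character_, n0)
  if (config$drop_first_block) {
    hit <- keep & table$block == 1L
    rule[hit] <- "first_block"
    keep <- keep & !hit
  }
  hit <- keep & table$rt < config$rt_min
  rule[hit] <- "rt_min"; keep <- keep & !hit
  hit <- keep & table$rt > config$rt_max
  rule[hit] <- "rt_max"; keep <- keep & !hit
  n_removed <- c(first_block = sum(rule == "first_block", na.rm = TRUE),
                 rt_min = sum(rule == "rt_min", na.rm = TRUE),
                 rt_max = sum(rule == "rt_max", na.rm = TRUE))
  report <- tibble::tibble(rule = names(n_removed),
                           removed = as.integer(n_removed))
  out <- table[keep, , drop = FALSE]
  attr(out, "trial_report") <- report
  attr(out, "n_input_trials") <- n0
  attr(out, "trials_excluded") <- TRUE
  attr(out, "exclusion_config") <- config
  out
}

#' Participant-level exclusions
#'
#' Computes accuracy and eligible-trial counts on the post-trial-exclusion
#' data and removes participants whose accuracy is strictly below
#' `min_accuracy` (rule `accuracy`, checked first) or whose eligible-trial
#' count is strictly below `min_eligible_trials` (rule `min_trials`). Each
#' excluded participant is tagged with the first failing rule only.
#'
#' @param table A tibble returned by [exclude_trials()].
#' @param config An [exclusion_config()].
#' @return The kept tibble; participant report and preprocessing flag
#'   attached.
#' @export
exclude_participants <- function(table, config = exclusion_config()) {
  if (!isTRUE(attr(table, "trials_excluded"))) {
    abort("exclude_participants() must be called on the output of exclude_trials()",
          class = "rrddm_order_error")
  }
  stopifnot(inherits(config, "exclusion_config"))
  stats <- table |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(n_eligible = dplyr::n(),
                     accuracy = mean(.data$response), .groups = "drop") |>
    dplyr::mutate(
      rule = dplyr::case_when(
        .data$accuracy < config$min_accuracy ~ "accuracy",
        .data$n_eligible < config$min_eligible_trials ~ "min_trials",
        TRUE ~ NA_character_
      ),
      kept = is.na(.data$rule)
    )
  out <- table[table$participant_id %in% stats$participant_id[stats$kept], ,
               drop = FALSE]
  for (at in c("trial_report", "n_input_trials", "trials_excluded",
               "exclusion_config")) {
    attr(out, at) <- attr(table, at)
  }
  attr(out, "participant_report") <- stats
  attr(out, "preprocessed") <- TRUE
  out
}

#' Apply the full preregistered exclusion pipeline
#'
#' [exclude_trials()] then [exclude_participants()], in that fixed order.
#' Idempotent: reapplying removes nothing further.
#'
#' @inheritParams exclude_trials
#' @return The preprocessed trial tibble with the full report attached;
#'   retrieve it with [exclusion_report()].
#' @export
apply_exclusions <- function(table, config = exclusion_config()) {
  table |> exclude_trials(config) |> exclude_participants(config)
}

#' Exclusion report
#'
#' Per-rule trial removal counts, per-participant eligibility statistics with
#' the triggering rule, the rule ordering, and conservation totals.
#'
#' @param table A table processed by [apply_exclusions()].
#' @return An `exclusion_report` (list of tibbles).
#' @export
exclusion_report <- function(table) {
  if (!isTRUE(attr(table, "preprocessed"))) {
    abort("no exclusion report: table has not been preprocessed",
          class = "rrddm_order_error")
  }
  pr <- attr(table, "participant_report")
  removed_part <- sum(pr$n_eligible[!pr$kept])
  structure(
    list(
      trials = attr(table, "trial_report"),
      participants = pr,
      ordering = c("first_block", "rt_min", "rt_max", "accuracy", "min_trials"),
      n_input_trials = attr(table, "n_input_trials"),
      n_kept_trials = nrow(table),
      n_removed_trials = sum(attr(table, "trial_report")$removed) + removed_part,
      n_excluded_participants = sum(!pr$kept),
      config = attr(table, "exclusion_config")
    ),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat(sprintf("  trials: %d in, %d kept\n", x$n_input_trials, x$n_kept_trials))
  print(x$trials)
  cat(sprintf("  participants excluded: %d\n", x$n_excluded_participants))
  invisible(x)
}

is_preprocessed <- function(table) isTRUE(attr(table, "preprocessed"))
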