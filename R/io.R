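trial_cols <- c("participant_id", "group", "block", "trial", "rt", "response")

#' Write a trial table to CSV
#'
#' Writes exactly the canonical header
#' `participant_id,group,block,trial,rt,response` so that a round trip
#' through [read_trials()] is lossless.
#'
#' @param table A trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path) {
  validate_trial_table(table)
  readr::write_csv(table[trial_cols], path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the header and the column domains (`rt` positive numeric,
#' `response` in {0, 1}, positive integer block/trial indices) and reports
#' the offending column and row on failure.
#'
#' @param path CSV file path.
#' @return A trial tibble.
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 1)
  if (!identical(header, paste(trial_cols, collapse = ","))) {
    abort(paste0("trial CSV must have exactly the columns: ",
                 paste(trial_cols, collapse = ",")),
          class = "rrddm_format_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    block = readr::col_integer(),
    trial = readr::col_integer(),
    rt = readr::col_double(),
    response = readr::col_integer()
  ))
  if (!identical(names(raw), trial_cols)) {
    abort(paste0("trial CSV must have exactly the columns: ",
                 paste(trial_cols, collapse = ",")),
          class = "rrddm_format_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed value in column `%s`, row %d",
                  probs$col[1], probs$row[1]),
          class = "rrddm_format_error")
  }
  validate_trial_table(raw)
  raw
}

validate_trial_table <- function(table) {
  if (!is.data.frame(table)) {
    abort("trial table must be a data frame", class = "rrddm_format_error")
  }
  missing <- setdiff(trial_cols, names(table))
  if (length(missing)) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rrddm_format_error")
  }
  fail_at <- function(col, bad) {
    if (any(bad)) {
      abort(sprintf("invalid value in column `%s`, row %d",
                    col, which(bad)[1]),
            class = "rrddm_format_error")
    }
  }
  fail_at("rt", !is.finite(table$rt) | table$rt <= 0)
  fail_at("response", !(table$response %in% c(0L, 1L)))
  fail_at("block", !is.finite(table$block) | table$block < 1 |
            table$block != round(table$block))
  fail_at("trial", !is.finite(table$trial) | table$trial < 1 |
            table$trial != round(table$trial))
  fail_at("group", !(table$group %in% c("fixed_time", "fixed_trial")))
  invisible(table)
}
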