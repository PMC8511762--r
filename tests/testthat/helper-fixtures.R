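# Shared fixtures: everything is generated in code at test time.

quick_design <- function(n_per_group = 2, n_blocks = 4, fixed_trials = 8,
                         fixed_time = 15, overhead = 1.0) {
  experiment_design(n_per_group = n_per_group, n_blocks = n_blocks,
                    fixed_trials = fixed_trials, fixed_time = fixed_time,
                    timing = trial_timing(overhead))
}

quick_config <- function(n_chains = 10, n_iter = 120, burn_in = 60, ...) {
  de_config(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in, ...)
}

two_participants <- function(group = "fixed_time") {
  tibble::tibble(participant_id = c("p1", "p2"), group = group)
}

# small hand-built trial table (valid domains, two participants, two groups)
mini_trials <- function(n_per_block = 5, blocks = 1:3) {
  grid <- expand.grid(block = blocks, trial = seq_len(n_per_block))
  make <- function(pid, group, rt_base) {
    tibble::tibble(participant_id = pid, group = group,
                   block = as.integer(grid$block),
                   trial = as.integer(grid$trial),
                   rt = rt_base + 0.01 * seq_len(nrow(grid)),
                   response = rep_len(c(1L, 1L, 0L, 1L), nrow(grid)))
  }
  dplyr::bind_rows(make("p1", "fixed_time", 0.4),
                   make("p2", "fixed_trial", 0.5))
}
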