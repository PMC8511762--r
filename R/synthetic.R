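#' Experiment design for synthetic datasets
#'
#' Describes the structure of the two-group block design: equal groups of
#' participants whose blocks terminate either after a fixed number of trials
#' (`fixed_trial` group) or after a fixed amount of time (`fixed_time`
#' group). Defaults mirror the study conditions the generator emulates:
#' 35 participants per group and 20 blocks.
#'
#' @param n_per_group Participants per group.
#' @param n_blocks Blocks per participant.
#' @param fixed_trials Trials per block in the fixed-trial group.
#' @param fixed_time Block duration in seconds in the fixed-time group.
#' @param timing A [trial_timing()] object; its overhead is both the
#'   reward-rate dead time and the per-trial accrual cost during fixed-time
#'   blocks.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(n_per_group = 35, n_blocks = 20,
                              fixed_trials = 30, fixed_time = 60,
                              timing = trial_timing()) {
  ok <- n_per_group >= 0 && n_per_group == round(n_per_group) &&
    n_blocks >= 1 && n_blocks == round(n_blocks) &&
    fixed_trials >= 1 && fixed_time > 0
  if (!ok) {
    abort("invalid design: counts must be non-negative integers, durations > 0",
          class = "rrddm_config_error")
  }
  stopifnot(inherits(timing, "trial_timing"))
  structure(
    list(n_per_group = n_per_group, n_blocks = n_blocks,
         fixed_trials = fixed_trials, fixed_time = fixed_time,
         timing = timing),
    class = "experiment_design"
  )
}

#' Group-level generating population
#'
#' Truncated-normal populations for the individual diffusion parameters, plus
#' a block-threshold trajectory. Two trajectory modes:
#'
#' * default: the initial threshold is drawn from its own truncated normal
#'   and decays exponentially toward the participant's reward-rate-optimal
#'   threshold, `a_ij = a*_i + (a_i1 - a*_i) exp(-lambda (j - 1))`. With
#'   `lambda = 0` thresholds are constant at the initial draw. This gives
#'   synthetic data the qualitative approach-to-optimality structure.
#' * offset mode (`c_offset = c(mean, sd)`): every block threshold is
#'   `a*_i + c_i` with `c_i ~ Normal(mean, sd)`; used to plant a known
#'   group-level distance-from-optimality for the quantitative hypotheses.
#'
#' Each of `v`, `zr`, `ter`, `a_init` is given as `c(location, scale, lower,
#' upper)` of a truncated normal. Defaults are typical of practiced random-dot
#' motion performance on the `s = 1` scale.
#'
#' @param v,zr,ter,a_init Truncated-normal specs `c(loc, scale, lower, upper)`.
#' @param lambda Convergence rate toward the optimal threshold, per block,
#'   `>= 0`.
#' @param c_offset Optional `c(mean, sd)` switching to offset mode.
#' @return A `group_population` object.
#' @export
group_population <- function(v = c(2.2, 0.4, 0.5, 5),
                             zr = c(0.5, 0.04, 0.3, 0.7),
                             ter = c(0.3, 0.05, 0.05, 0.8),
                             a_init = c(2.5, 0.5, 0.5, 5),
                             lambda = 0.15,
                             c_offset = NULL) {
  chk <- function(x, nm) {
    if (length(x) != 4 || x[2] <= 0) {
      abort(paste0("`", nm, "` must be c(loc, scale > 0, lower, upper)"),
            class = "rrddm_config_error")
    }
    if (x[3] >= x[4]) {
      abort(paste0("`", nm, "`: truncation lower bound must be below upper"),
            class = "rrddm_config_error")
    }
  }
  chk(v, "v"); chk(zr, "zr"); chk(ter, "ter"); chk(a_init, "a_init")
  if (lambda < 0) abort("`lambda` must be >= 0", class = "rrddm_config_error")
  if (!is.null(c_offset) && (length(c_offset) != 2 || c_offset[2] < 0)) {
    abort("`c_offset` must be c(mean, sd >= 0)", class = "rrddm_config_error")
  }
  structure(
    list(v = v, zr = zr, ter = ter, a_init = a_init, lambda = lambda,
         c_offset = c_offset),
    class = "group_population"
  )
}

draw_tn <- function(spec) rtnorm(1, spec[1], spec[2], spec[3], spec[4])

#' Draw one participant from a generating population
#'
#' Samples individual diffusion parameters from the population's truncated
#' normals and builds the per-block threshold trajectory (see
#' [group_population()] for the two modes). Uses the current RNG state;
#' seed at the caller.
#'
#' @param population A [group_population()].
#' @param design An [experiment_design()].
#' @param s Diffusion coefficient of the generating model.
#' @return A list with `params` (drift `v`, `zr`, `ter`), `a_star`, `c` (the
#'   offset draw, `NA` in trajectory mode) and `a_blocks` (length
#'   `design$n_blocks`).
#' @export
draw_participant <- function(population, design, s = 1) {
  stopifnot(inherits(population, "group_population"),
            inherits(design, "experiment_design"))
  v <- draw_tn(population$v)
  zr <- draw_tn(population$zr)
  ter <- draw_tn(population$ter)
  a_star <- optimal_threshold(v, ter, timing = design$timing, s = s)
  j <- seq_len(design$n_blocks)
  if (!is.null(population$c_offset)) {
    ci <- rnorm(1, population$c_offset[1], population$c_offset[2])
    a_blocks <- rep(max(a_star + ci, 0.05), design$n_blocks)
  } else {
    ci <- NA_real_
    a1 <- draw_tn(population$a_init)
    a_blocks <- a_star + (a1 - a_star) * exp(-population$lambda * (j - 1))
  }
  list(params = list(v = v, zr = zr, ter = ter), a_star = a_star,
       c = ci, a_blocks = a_blocks)
}

simulate_block <- function(v, a, zr, ter, s, rule, design) {
  if (rule == "fixed_trial") {
    sim <- simulate_ddm_cpp(design$fixed_trials, v, a, zr, ter, s,
                            0.001, TRUE, 300)
    return(tibble::tibble(rt = sim$rt, response = as.integer(sim$response)))
  }
  # fixed-time accrual: trials count while cumulative (rt + overhead) stays
  # below the block duration; at least one trial per block
  overhead <- design$timing$overhead
  rts <- numeric(0); resp <- integer(0)
  elapsed <- 0
  repeat {
    sim <- simulate_ddm_cpp(16L, v, a, zr, ter, s, 0.001, TRUE, 300)
    for (i in seq_len(16L)) {
      rts <- c(rts, sim$rt[i]); resp <- c(resp, sim$response[i])
      elapsed <- elapsed + sim$rt[i] + overhead
      if (elapsed >= design$fixed_time && length(rts) >= 1) {
        return(tibble::tibble(rt = rts, response = resp))
      }
    }
  }
}

#' Generate a synthetic two-group trial table
#'
#' Builds a full behavioural dataset with the study's structure: for each
#' group and participant, individual parameters drawn from the group
#' population, then per-block diffusion trials with the block's threshold.
#' Fixed-trial blocks contain exactly `design$fixed_trials` trials;
#' fixed-time blocks accrue trials while the cumulative trial time
#' (response time plus overhead) is below the block duration, never fewer
#' than one. Deterministic given `seed`.
#'
#' @param design An [experiment_design()].
#' @param populations Named list of [group_population()] objects for groups
#'   `fixed_time` and `fixed_trial`.
#' @param seed Integer seed.
#' @param s Diffusion coefficient of the generating model.
#' @return A tibble of trial records (`participant_id`, `group`, `block`,
#'   `trial`, `rt`, `response`) with the generating truth attached as
#'   `attr(, "truth")`: `$participants` (one row per participant with `v`,
#'   `zr`, `ter`, `a_star`, `c`) and `$thresholds` (per participant and
#'   block).
#' @examples
#' d <- generate_dataset(experiment_design(n_per_group = 1, n_blocks = 2,
#'                                         fixed_trials = 5, fixed_time = 10),
#'                       seed = 1)
#' @export
generate_dataset <- function(design = experiment_design(),
                             populations = list(
                               fixed_time = group_population(),
                               fixed_trial = group_population()
                             ),
                             seed = 1, s = 1) {
  stopifnot(inherits(design, "experiment_design"))
  if (!all(c("fixed_time", "fixed_trial") %in% names(populations))) {
    abort("`populations` must name groups fixed_time and fixed_trial",
          class = "rrddm_config_error")
  }
  rows <- list(); truth_p <- list(); truth_a <- list()
  withr::with_seed(seed, {
    for (g in c("fixed_time", "fixed_trial")) {
      pop <- populations[[g]]
      for (i in seq_len(design$n_per_group)) {
        pid <- sprintf("%s_%02d", g, i)
        dp <- draw_participant(pop, design, s = s)
        truth_p[[pid]] <- tibble::tibble(
          participant_id = pid, group = g,
          v = dp$params$v, zr = dp$params$zr, ter = dp$params$ter,
          a_star = dp$a_star, c = dp$c
        )
        truth_a[[pid]] <- tibble::tibble(
          participant_id = pid, group = g,
          block = seq_len(design$n_blocks), a = dp$a_blocks
        )
        for (j in seq_len(design$n_blocks)) {
          tr <- simulate_block(dp$params$v, dp$a_blocks[j], dp$params$zr,
                               dp$params$ter, s, g, design)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            participant_id = pid, group = g, block = j,
            trial = seq_len(nrow(tr)), rt = tr$rt, response = tr$response
          )
        }
      }
    }
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_trial_table()
  attr(out, "truth") <- list(
    participants = if (length(truth_p)) dplyr::bind_rows(truth_p) else NULL,
    thresholds = if (length(truth_a)) dplyr::bind_rows(truth_a) else NULL
  )
  out
}

empty_trial_table <- function() {
  tibble::tibble(participant_id = character(), group = character(),
                 block = integer(), trial = integer(),
                 rt = numeric(), response = integer())
}
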