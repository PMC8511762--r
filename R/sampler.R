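#' Differential-evolution MCMC configuration
#'
#' Defaults follow the preregistered estimation settings: 66 chains, 3,000
#' iterations per chain with the first 1,500 discarded as burn-in (no
#' thinning). The DE scale `gamma` defaults to `2.38 / sqrt(2 d)` for a
#' `d`-dimensional update, with a fraction `gamma1_prob` of proposals using
#' `gamma = 1` (mode jumping); proposals carry uniform jitter of half-width
#' `jitter`. With probability `migration_prob`, an iteration performs a
#' migration step instead of DE crossover.
#'
#' @param n_chains Number of chains (>= 4; DE needs distinct donors).
#' @param n_iter Total iterations per chain.
#' @param burn_in Iterations discarded from the front.
#' @param gamma DE scale, or `NULL` for `2.38 / sqrt(2 d)`.
#' @param jitter Half-width of the uniform proposal noise.
#' @param migration_prob Per-iteration probability of a migration step.
#' @param gamma1_prob Fraction of DE proposals with `gamma = 1`.
#' @return A `de_config` object.
#' @export
de_config <- function(n_chains = 66, n_iter = 3000, burn_in = 1500,
                      gamma = NULL, jitter = 1e-4, migration_prob = 0.05,
                      gamma1_prob = 0.1) {
  ok <- n_chains >= 4 && burn_in >= 0 && burn_in < n_iter &&
    jitter >= 0 && migration_prob >= 0 && migration_prob <= 1 &&
    gamma1_prob >= 0 && gamma1_prob <= 1
  if (!ok) {
    abort("invalid sampler config: need n_chains >= 4 and 0 <= burn_in < n_iter",
          class = "rrddm_config_error")
  }
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), gamma = gamma, jitter = jitter,
         migration_prob = migration_prob, gamma1_prob = gamma1_prob),
    class = "de_config"
  )
}

new_ddm_posterior <- function(draws, burn_in, config, acceptance, seed) {
  structure(
    list(draws = draws, burn_in = burn_in, config = config,
         acceptance = acceptance, seed = seed),
    class = "ddm_posterior"
  )
}

#' @export
print.ddm_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<ddm_posterior> %d chains x %d retained iterations x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  burn-in %d, mean acceptance %.2f\n",
              x$burn_in, mean(x$acceptance)))
  invisible(x)
}

#' Pooled draws as a matrix
#'
#' @param x A `ddm_posterior`.
#' @return Matrix of (chains x iterations) rows by parameter columns.
#' @export
posterior_matrix <- function(x) {
  stopifnot(inherits(x, "ddm_posterior"))
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(x$draws)[[3]]
  m
}

#' Tidy posterior draws into long format
#'
#' @param x A `ddm_posterior`.
#' @param ... Unused.
#' @return A tibble with `chain`, `iteration`, `parameter`, `value`.
#' @export
tidy.ddm_posterior <- function(x, ...) {
  d <- dim(x$draws)
  pn <- dimnames(x$draws)[[3]]
  tibble::tibble(
    chain = rep(seq_len(d[1]), times = d[2] * d[3]),
    iteration = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(pn, each = d[1] * d[2]),
    value = as.vector(x$draws)
  )
}

# One migration sweep over a state matrix: a random subset of chains is
# drawn; states travel around a random cycle and each transfer is accepted
# by a Metropolis test against the receiving chain's current state. A
# singleton subset leaves everything unchanged.
migration_core <- function(states, lps) {
  n <- nrow(states)
  k <- sample.int(n, 1)
  if (k < 2) return(list(states = states, lps = lps, moved = integer(0)))
  sel <- sample.int(n, k)
  old_states <- states[sel, , drop = FALSE]
  old_lps <- lps[sel]
  moved <- integer(0)
  for (i in seq_len(k)) {
    donor <- if (i == 1) k else i - 1
    recv <- sel[i]
    delta <- old_lps[donor] - lps[recv]
    if (is.finite(delta) && log(runif(1)) < delta) {
      states[recv, ] <- old_states[donor, ]
      lps[recv] <- old_lps[donor]
      moved <- c(moved, recv)
    }
  }
  list(states = states, lps = lps, moved = moved)
}

#' Migration step between DE-MCMC chains
#'
#' Proposes each selected chain's state to the next chain along a random
#' cycle and accepts by the Metropolis rule, leaving the target distribution
#' invariant. Used inside [run_de_mcmc()] to free stuck chains; exported for
#' inspection and testing. Uses the current RNG state.
#'
#' @param states Matrix of chain states (chains x parameters).
#' @param lps Log-posterior values of the rows of `states`.
#' @return A list with updated `states`, `lps`, and `moved` (indices of
#'   chains that accepted an incoming state).
#' @export
migration_step <- function(states, lps) {
  stopifnot(is.matrix(states), nrow(states) >= 2, length(lps) == nrow(states))
  migration_core(states, lps)
}

#' Differential-evolution MCMC
#'
#' Samples from an arbitrary target: per iteration and chain `k`, proposes
#' `theta_k + gamma (theta_m - theta_n) + U(-jitter, jitter)` with distinct
#' random donors `m, n != k` and accepts by the Metropolis rule; with
#' probability `migration_prob` the iteration performs a [migration_step()]
#' instead. Deterministic given `seed`.
#'
#' @param lp Log-density function of one parameter vector.
#' @param init Chain starts: a matrix (chains x parameters), a single
#'   vector (replicated with jitter), or a function drawing one start
#'   vector (re-drawn up to 1000 times per chain until the log posterior is
#'   finite).
#' @param config A [de_config()].
#' @param seed Integer seed.
#' @return A `ddm_posterior` with draws of shape chains x retained
#'   iterations x parameters.
#' @examples
#' post <- run_de_mcmc(function(x) dnorm(x, log = TRUE), init = rnorm(1),
#'                     config = de_config(n_chains = 8, n_iter = 200,
#'                                        burn_in = 100), seed = 1)
#' @export
run_de_mcmc <- function(lp, init, config = de_config(), seed = 1) {
  stopifnot(inherits(config, "de_config"))
  nc <- config$n_chains
  withr::with_seed(seed, {
    states <- de_init(lp, init, nc)
    d <- ncol(states)
    lps <- apply(states, 1, lp)
    if (any(!is.finite(lps))) {
      abort("no finite-log-posterior start found for some chains: the prior and likelihood may conflict",
            class = "rrddm_init_error")
    }
    gamma0 <- config$gamma %||% (2.38 / sqrt(2 * d))
    retain <- config$n_iter - config$burn_in
    draws <- array(NA_real_, dim = c(nc, retain, d))
    dimnames(draws) <- list(NULL, NULL, colnames(states))
    acc <- integer(nc); att <- integer(nc)
    for (it in seq_len(config$n_iter)) {
      if (nc >= 2 && runif(1) < config$migration_prob) {
        mg <- migration_core(states, lps)
        states <- mg$states; lps <- mg$lps
      } else {
        for (k in seq_len(nc)) {
          don <- sample.int(nc - 1L, 2L)
          don <- ifelse(don >= k, don + 1L, don)
          g <- if (runif(1) < config$gamma1_prob) 1 else gamma0
          prop <- states[k, ] + g * (states[don[1], ] - states[don[2], ]) +
            runif(d, -config$jitter, config$jitter)
          lp_prop <- lp(prop)
          att[k] <- att[k] + 1L
          if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lps[k]) {
            states[k, ] <- prop
            lps[k] <- lp_prop
            acc[k] <- acc[k] + 1L
          }
        }
      }
      if (it > config$burn_in) draws[, it - config$burn_in, ] <- states
    }
    new_ddm_posterior(draws, config$burn_in, config,
                      acceptance = ifelse(att > 0, acc / att, NA_real_),
                      seed = seed)
  })
}

de_init <- function(lp, init, nc) {
  if (is.function(init)) {
    states <- NULL
    for (k in seq_len(nc)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        th <- init()
        if (is.finite(lp(th))) { ok <- TRUE; break }
      }
      if (!ok) {
        abort("no finite-log-posterior start found in 1000 prior draws",
              class = "rrddm_init_error")
      }
      if (is.null(states)) {
        states <- matrix(NA_real_, nc, length(th),
                         dimnames = list(NULL, names(th)))
      }
      states[k, ] <- th
    }
    return(states)
  }
  if (is.matrix(init)) {
    if (nrow(init) != nc) {
      abort("init matrix must have one row per chain",
            class = "rrddm_init_error")
    }
    return(init)
  }
  init <- as.numeric(init)
  states <- matrix(rep(init, each = nc), nrow = nc,
                   dimnames = list(NULL, names(init)))
  states + matrix(rnorm(nc * length(init), 0, pmax(abs(init), 1) * 0.1),
                  nrow = nc)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed after splitting each chain in half, per
#' parameter. Values near 1 indicate between-chain agreement; the fitting
#' pipeline warns (but does not abort) above 1.1.
#'
#' @param x A `ddm_posterior`, or a chains x iterations (x parameters)
#'   array.
#' @return A tibble with `parameter` and `rhat`.
#' @export
rhat <- function(x) {
  a <- if (inherits(x, "ddm_posterior")) x$draws else x
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1))
  d <- dim(a)
  if (d[1] < 2) abort("R-hat needs at least 2 chains", class = "rrddm_diag_error")
  if (d[2] < 50) {
    abort("R-hat needs at least 50 retained iterations per chain",
          class = "rrddm_diag_error")
  }
  half <- floor(d[2] / 2)
  pn <- dimnames(a)[[3]] %||% paste0("par", seq_len(d[3]))
  out <- vapply(seq_len(d[3]), function(j) {
    seqs <- rbind(a[, seq_len(half), j],
                  a[, half + seq_len(half), j])
    w <- mean(apply(seqs, 1, var))
    b <- half * var(rowMeans(seqs))
    vp <- (half - 1) / half * w + b / half
    if (w <= 0) return(if (b > 0) Inf else 1)
    sqrt(vp / w)
  }, numeric(1))
  tibble::tibble(parameter = pn, rhat = out)
}
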