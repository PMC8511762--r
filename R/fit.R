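# Hierarchical fitting: DE-MCMC with blocked updates. Each iteration
# updates the group-level parameters and then each participant's parameters
# in conditional sub-steps, exploiting the conditional independence of
# participants given the group level. Cached posterior components (hyperprior
# H, per-participant individual prior P_i, per-participant likelihood L_i)
# make a block update recompute only what it touches.

run_blocked_de <- function(comps, config, seed) {
  nc <- config$n_chains
  np <- comps$n_pars
  npart <- comps$n_participants
  nlb <- comps$n_like_blocks

  # update schedule: hyper block, then per participant a scalar sub-block
  # and one sub-block per modelled block (empty for the offset models)
  sched <- list(list(type = "hyper", idx = comps$hyper_idx))
  for (i in seq_len(npart)) {
    sched[[length(sched) + 1L]] <- list(type = "scalar", i = i,
                                        idx = comps$scalar_idx[[i]])
    for (j in seq_along(comps$blockpar_idx[[i]])) {
      idx <- comps$blockpar_idx[[i]][[j]]
      if (length(idx)) {
        sched[[length(sched) + 1L]] <- list(type = "blockpar", i = i, j = j,
                                            idx = idx)
      }
    }
  }
  gamma_s <- vapply(sched, function(b) {
    config$gamma %||% (2.38 / sqrt(2 * length(b$idx)))
  }, numeric(1))

  withr::with_seed(seed, {
    states <- matrix(NA_real_, nc, np, dimnames = list(NULL, comps$names))
    H <- numeric(nc)
    P <- matrix(NA_real_, nc, npart)
    L <- array(NA_real_, dim = c(nc, npart, nlb))
    refresh_chain <- function(k, th) {
      h <- comps$lp_hyper(th)
      if (!is.finite(h)) return(FALSE)
      p <- vapply(seq_len(npart), function(i) comps$lp_ind(th, i), numeric(1))
      if (any(!is.finite(p))) return(FALSE)
      l <- matrix(NA_real_, npart, nlb)
      for (i in seq_len(npart)) {
        for (j in seq_len(nlb)) l[i, j] <- comps$lp_like_block(th, i, j)
      }
      if (any(!is.finite(l))) return(FALSE)
      states[k, ] <<- th; H[k] <<- h; P[k, ] <<- p; L[k, , ] <<- l
      TRUE
    }
    for (k in seq_len(nc)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        if (refresh_chain(k, comps$init_draw())) { ok <- TRUE; break }
      }
      if (!ok) {
        abort("no finite-log-posterior initial state found in 1000 prior draws",
              class = "rrddm_init_error")
      }
    }

    retain <- config$n_iter - config$burn_in
    draws <- array(NA_real_, dim = c(nc, retain, np),
                   dimnames = list(NULL, NULL, comps$names))
    acc <- 0L; att <- 0L
    for (it in seq_len(config$n_iter)) {
      if (nc >= 2 && runif(1) < config$migration_prob) {
        lps <- H + rowSums(P) + rowSums(L, dims = 1)
        mg <- migration_core(states, lps)
        # refresh caches of chains that accepted an incoming state
        for (k in mg$moved) refresh_chain(k, mg$states[k, ])
      } else {
        for (b in seq_along(sched)) {
          upd <- sched[[b]]
          idx <- upd$idx
          d_b <- length(idx)
          for (k in seq_len(nc)) {
            don <- sample.int(nc - 1L, 2L)
            don <- ifelse(don >= k, don + 1L, don)
            g <- if (runif(1) < config$gamma1_prob) 1 else gamma_s[b]
            th <- states[k, ]
            th[idx] <- th[idx] + g * (states[don[1], idx] - states[don[2], idx]) +
              runif(d_b, -config$jitter, config$jitter)
            att <- att + 1L
            if (upd$type == "hyper") {
              h_new <- comps$lp_hyper(th)
              if (!is.finite(h_new)) next
              p_new <- vapply(seq_len(npart), function(i) comps$lp_ind(th, i),
                              numeric(1))
              delta <- (h_new + sum(p_new)) - (H[k] + sum(P[k, ]))
              if (is.finite(delta) && log(runif(1)) < delta) {
                states[k, idx] <- th[idx]
                H[k] <- h_new; P[k, ] <- p_new
                acc <- acc + 1L
              }
            } else if (upd$type == "scalar") {
              i <- upd$i
              p_new <- comps$lp_ind(th, i)
              if (!is.finite(p_new)) next
              l_new <- vapply(seq_len(nlb), function(j) {
                comps$lp_like_block(th, i, j)
              }, numeric(1))
              delta <- (p_new + sum(l_new)) - (P[k, i] + sum(L[k, i, ]))
              if (is.finite(delta) && log(runif(1)) < delta) {
                states[k, idx] <- th[idx]
                P[k, i] <- p_new; L[k, i, ] <- l_new
                acc <- acc + 1L
              }
            } else {
              i <- upd$i; j <- upd$j
              p_new <- comps$lp_ind(th, i)
              if (!is.finite(p_new)) next
              l_new <- comps$lp_like_block(th, i, j)
              delta <- (p_new + l_new) - (P[k, i] + L[k, i, j])
              if (is.finite(delta) && log(runif(1)) < delta) {
                states[k, idx] <- th[idx]
                P[k, i] <- p_new; L[k, i, j] <- l_new
                acc <- acc + 1L
              }
            }
          }
        }
      }
      if (it > config$burn_in) draws[, it - config$burn_in, ] <- states
    }
    new_ddm_posterior(draws, config$burn_in, config,
                      acceptance = rep(acc / max(att, 1L), nc), seed = seed)
  })
}

#' Fit a hierarchical diffusion model
#'
#' Estimates one of the four hierarchical model structures by
#' differential-evolution MCMC with migration, using blocked group-level /
#' per-participant updates. The input table must have been through
#' [apply_exclusions()] (the preregistered pipeline order); pass a table
#' prepared with [no_exclusions()] to fit without exclusions.
#'
#' @param data A preprocessed trial tibble.
#' @param model One of `"block_threshold"`, `"optimality_offset"`,
#'   `"group_difference"`, `"block_threshold_drift"`.
#' @param group For `optimality_offset`: which group to fit.
#' @param blocks Blocks to model; defaults to all blocks present (block
#'   models) or blocks 11-20 (optimality models).
#' @param config A [de_config()].
#' @param priors Prior overrides, see [default_priors()].
#' @param timing A [trial_timing()] (optimality models).
#' @param s Diffusion coefficient.
#' @param seed Integer seed; fits are exactly reproducible.
#' @param warn_rhat Warn if any split R-hat exceeds this (set `Inf` to
#'   disable).
#' @return A `ddm_fit`: list with `spec`, `samples` (a `ddm_posterior`),
#'   `config`, `seed`, `rhat`, `runtime`.
#' @export
fit_ddm <- function(data, model = c("block_threshold", "optimality_offset",
                                    "group_difference",
                                    "block_threshold_drift"),
                    group = NULL, blocks = NULL, config = de_config(),
                    priors = NULL, timing = trial_timing(), s = 1, seed = 1,
                    warn_rhat = 1.1) {
  model <- match.arg(model)
  if (!is_preprocessed(data)) {
    abort("data must be preprocessed with apply_exclusions() before fitting (use no_exclusions() to keep everything)",
          class = "rrddm_order_error")
  }
  data <- tibble::as_tibble(data)
  if (model == "optimality_offset") {
    if (is.null(group)) {
      abort("`group` is required for the optimality-offset model",
            class = "rrddm_input_error")
    }
    data <- data[data$group == group, , drop = FALSE]
    if (!nrow(data)) {
      abort(paste0("no data for group ", group), class = "rrddm_input_error")
    }
  }
  present <- sort(unique(data$block))
  spec <- switch(
    model,
    block_threshold = spec_block_threshold(data, blocks %||% present,
                                           priors, s),
    block_threshold_drift = spec_block_threshold_drift(data,
                                                       blocks %||% present,
                                                       priors, s),
    optimality_offset = spec_optimality_offset(
      data, timing, blocks %||% intersect(11:20, present), priors, s),
    group_difference = spec_group_difference(
      data, timing, blocks %||% intersect(11:20, present), priors, s)
  )
  fit_ddm_spec(data, spec, config, seed, warn_rhat)
}

#' Fit a prebuilt model spec
#'
#' Lower-level entry point taking an explicit `ddm_model_spec`.
#' @inheritParams fit_ddm
#' @param spec A `ddm_model_spec`.
#' @return A `ddm_fit`.
#' @export
fit_ddm_spec <- function(data, spec, config = de_config(), seed = 1,
                         warn_rhat = 1.1) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  comps <- lp_components(spec, data)
  t0 <- proc.time()["elapsed"]
  samples <- run_blocked_de(comps, config, seed)
  runtime <- as.numeric(proc.time()["elapsed"] - t0)
  rh <- tryCatch(rhat(samples), error = function(e) NULL)
  if (!is.null(rh) && is.finite(warn_rhat) && any(rh$rhat > warn_rhat)) {
    warn(sprintf("%d parameter(s) have split R-hat above %.2f (max %.3f)",
                 sum(rh$rhat > warn_rhat), warn_rhat, max(rh$rhat)))
  }
  structure(
    list(spec = spec, samples = samples, config = config, seed = seed,
         rhat = rh, runtime = runtime),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> %s: %d parameters, %d chains x %d retained iterations (%.1f s)\n",
              x$spec$model_id, n_free_parameters(x$spec),
              x$config$n_chains, x$config$n_iter - x$config$burn_in,
              x$runtime))
  if (!is.null(x$rhat)) {
    cat(sprintf("  max split R-hat %.3f\n", max(x$rhat$rhat)))
  }
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior median, mean, sd,
#'   95% credible interval, and split R-hat.
#' @export
tidy.ddm_fit <- function(x, ...) {
  m <- posterior_matrix(x$samples)
  out <- tibble::tibble(
    parameter = colnames(m),
    median = apply(m, 2, median),
    mean = colMeans(m),
    sd = apply(m, 2, sd),
    ci_low = apply(m, 2, quantile, 0.025),
    ci_high = apply(m, 2, quantile, 0.975)
  )
  if (!is.null(x$rhat)) out <- dplyr::left_join(out, x$rhat, by = "parameter")
  dplyr::left_join(out,
                   dplyr::select(x$spec$pars, "name", "role", "param",
                                 "group", "participant", "block"),
                   by = c(parameter = "name"))
}

#' One-row fit summary
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return A tibble with model id, dimensions, acceptance, max R-hat,
#'   runtime.
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model_id,
    n_participants = nrow(x$spec$participants),
    n_parameters = n_free_parameters(x$spec),
    n_chains = x$config$n_chains,
    n_retained = x$config$n_iter - x$config$burn_in,
    acceptance = mean(x$samples$acceptance),
    max_rhat = if (is.null(x$rhat)) NA_real_ else max(x$rhat$rhat),
    runtime_s = x$runtime
  )
}

# pooled post-burn-in draws of one named parameter
parameter_draws <- function(fit, parameter) {
  m <- posterior_matrix(fit$samples)
  if (!parameter %in% colnames(m)) {
    abort(paste0("no parameter named ", parameter),
          class = "rrddm_input_error")
  }
  m[, parameter]
}
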