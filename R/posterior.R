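# Joint log posterior of a hierarchical model spec, decomposed into the
# pieces the blocked sampler needs: a hyperprior term, per-participant
# individual-prior terms (conditional on the group level), and
# per-participant likelihood terms. A block update then recomputes only the
# components it touches.

#' Pack named parameters into the spec's flat vector
#'
#' @param spec A `ddm_model_spec`.
#' @param values Named numeric vector or list covering every parameter.
#' @return Numeric vector in the spec's packing order.
#' @export
pack_parameters <- function(spec, values) {
  values <- unlist(values)
  missing <- setdiff(spec$pars$name, names(values))
  if (length(missing)) {
    abort(paste0("missing parameter value(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "rrddm_packing_error")
  }
  out <- as.numeric(values[spec$pars$name])
  names(out) <- spec$pars$name
  out
}

#' Unpack a flat vector into a named tibble
#'
#' @inheritParams pack_parameters
#' @param theta Flat parameter vector in packing order.
#' @return The spec's parameter table with a `value` column.
#' @export
unpack_parameters <- function(spec, theta) {
  check_theta(spec, theta)
  dplyr::mutate(spec$pars, value = as.numeric(theta))
}

check_theta <- function(spec, theta) {
  if (length(theta) != nrow(spec$pars)) {
    abort(sprintf("parameter vector has length %d; spec packs %d parameters",
                  length(theta), nrow(spec$pars)),
          class = "rrddm_packing_error")
  }
  invisible(theta)
}

# Memoised reward-rate-optimal threshold, keyed on (v, ter) rounded to 1e-6;
# bounds the cost of the deterministic node inside the posterior.
make_astar_memo <- function(timing, s) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(v, ter) {
    key <- sprintf("%.6f|%.6f", v, ter)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- optimal_threshold_cpp(v, ter, timing$overhead, s, 10, 1e-6)
    cache[[key]] <- val
    val
  }
}

# Build the posterior evaluator set for one spec + dataset.
lp_components <- function(spec, data) {
  pars <- spec$pars
  nm <- pars$name
  np <- nrow(pars)
  offset_model <- spec$model_id %in% c("optimality_offset", "group_difference")

  data <- tibble::as_tibble(data)
  check_trial_columns(data, c("participant_id", "block", "rt", "response"))
  extra_blocks <- setdiff(unique(data$block), spec$blocks)
  if (!offset_model && length(extra_blocks)) {
    # the offset models window the data on purpose; the block models need a
    # threshold parameter for every block they are asked to explain
    abort(paste0("data contain blocks the spec does not model: ",
                 paste(head(extra_blocks, 5), collapse = ", ")),
          class = "rrddm_spec_error")
  }
  data <- data[data$block %in% spec$blocks, , drop = FALSE]
  pid <- spec$participants$participant_id
  if (!all(pid %in% data$participant_id)) {
    abort("data contain no modelled trials for some participants",
          class = "rrddm_input_error")
  }

  hyper_idx <- which(pars$role == "hyper")
  h_loc <- pars$prior_loc[hyper_idx]
  h_sc <- pars$prior_scale[hyper_idx]
  h_lo <- pars$prior_lower[hyper_idx]
  h_hi <- pars$prior_upper[hyper_idx]

  ind_all <- which(pars$role == "individual")
  hl_all <- match(pars$hyper_loc[ind_all], nm)   # NA for tied c offsets
  hs_all <- match(pars$hyper_scale[ind_all], nm)
  lo_all <- pars$lower[ind_all]
  hi_all <- pars$upper[ind_all]
  part_of <- match(pars$participant[ind_all], pid)
  c_rows <- which(pars$param[ind_all] == "c" & is.na(hl_all))
  i_mub <- match("mu_c_bar", nm)
  i_dc <- match("delta_c", nm)
  c_sign <- if (length(c_rows)) {
    ifelse(pars$group[ind_all][c_rows] == "fixed_time", 0.5, -0.5)
  } else numeric(0)

  ind_by_p <- lapply(seq_along(pid), function(i) ind_all[part_of == i])
  rows_by_p <- lapply(seq_along(pid), function(i) which(part_of == i))

  # per-participant data caches, with per-block trial subsets so that a
  # block-threshold update only re-evaluates its own block's likelihood
  nb <- length(spec$blocks)
  dat <- lapply(pid, function(p) {
    d <- data[data$participant_id == p, , drop = FALSE]
    slot <- match(d$block, spec$blocks)
    by_block <- lapply(seq_len(nb), function(j) {
      sel <- slot == j
      list(rt = as.numeric(d$rt[sel]), resp = as.integer(d$response[sel]),
           n = sum(sel))
    })
    list(rt = as.numeric(d$rt), resp = as.integer(d$response),
         slot = slot, n = nrow(d), by_block = by_block)
  })

  # likelihood parameter lookups
  i_v <- match(paste0("v[", pid, "]"), nm)
  i_zr <- match(paste0("zr[", pid, "]"), nm)
  i_ter <- match(paste0("ter[", pid, "]"), nm)
  i_c <- match(paste0("c[", pid, "]"), nm)
  a_by_p <- lapply(pid, function(p) {
    match(sprintf("a[%s,%d]", p, spec$blocks), nm)
  })
  v_by_p <- lapply(pid, function(p) {
    match(sprintf("v[%s,%d]", p, spec$blocks), nm)
  })
  block_drift <- spec$model_id == "block_threshold_drift"
  s <- spec$s
  astar <- if (offset_model) make_astar_memo(spec$timing, s) else NULL

  ind_locs <- function(theta, rows) {
    loc <- theta[hl_all[rows]]
    if (length(c_rows)) {
      in_c <- rows %in% c_rows
      if (any(in_c)) {
        loc[in_c] <- theta[i_mub] +
          c_sign[match(rows[in_c], c_rows)] * theta[i_dc]
      }
    }
    loc
  }

  lp_hyper <- function(theta) {
    sum(dtnorm_log(theta[hyper_idx], h_loc, h_sc, h_lo, h_hi))
  }

  lp_ind <- function(theta, i) {
    rows <- rows_by_p[[i]]
    sc <- theta[hs_all[rows]]
    if (any(sc <= 0)) return(-Inf)
    sum(dtnorm_log(theta[ind_all[rows]], ind_locs(theta, rows), sc,
                   lo_all[rows], hi_all[rows]))
  }

  lp_like <- function(theta, i) {
    d <- dat[[i]]
    if (d$n == 0) return(0)
    if (offset_model) {
      v <- theta[i_v[i]]; ter <- theta[i_ter[i]]
      if (v <= 0) return(-Inf)
      a <- astar(v, ter) + theta[i_c[i]]
      if (a <= 0) return(-Inf)
      return(ddm_loglik_cpp(d$rt, d$resp, rep(v, d$n), rep(a, d$n),
                            0.5, ter, s, 1e-10, 1e-7))
    }
    a <- theta[a_by_p[[i]]][d$slot]
    v <- if (block_drift) theta[v_by_p[[i]]][d$slot] else rep(theta[i_v[i]], d$n)
    ddm_loglik_cpp(d$rt, d$resp, v, a, theta[i_zr[i]], theta[i_ter[i]],
                   s, 1e-10, 1e-7)
  }

  # likelihood of one participant's trials within one modelled block
  # (block models only; offset models have a single shared threshold)
  lp_like_block <- function(theta, i, j) {
    if (offset_model) return(lp_like(theta, i))
    db <- dat[[i]]$by_block[[j]]
    if (db$n == 0) return(0)
    a <- rep(theta[a_by_p[[i]][j]], db$n)
    v <- if (block_drift) rep(theta[v_by_p[[i]][j]], db$n) else
      rep(theta[i_v[i]], db$n)
    ddm_loglik_cpp(db$rt, db$resp, v, a, theta[i_zr[i]], theta[i_ter[i]],
                   s, 1e-10, 1e-7)
  }

  # conditional update schedule for the blocked sampler: participant-level
  # scalar parameters, then one sub-block per modelled block
  if (offset_model) {
    scalar_idx <- lapply(seq_along(pid), function(i) ind_by_p[[i]])
    blockpar_idx <- lapply(seq_along(pid), function(i) list())
  } else {
    scalar_idx <- lapply(seq_along(pid), function(i) {
      rows <- ind_by_p[[i]]
      rows[is.na(pars$block[rows])]
    })
    blockpar_idx <- lapply(seq_along(pid), function(i) {
      lapply(seq_len(nb), function(j) {
        rows <- ind_by_p[[i]]
        rows[!is.na(pars$block[rows]) & pars$block[rows] == spec$blocks[j]]
      })
    })
  }

  total <- function(theta) {
    h <- lp_hyper(theta)
    if (!is.finite(h)) return(-Inf)
    out <- h
    for (i in seq_along(pid)) {
      p <- lp_ind(theta, i)
      if (!is.finite(p)) return(-Inf)
      l <- lp_like(theta, i)
      if (!is.finite(l)) return(-Inf)
      out <- out + p + l
    }
    out
  }

  init_draw <- function() {
    theta <- numeric(np)
    theta[hyper_idx] <- rtnorm(length(hyper_idx), h_loc, h_sc, h_lo, h_hi)
    sc <- theta[hs_all]
    sc[sc <= 0] <- 1e-3
    theta[ind_all] <- rtnorm(length(ind_all), ind_locs(theta, seq_along(ind_all)),
                             sc, lo_all, hi_all)
    names(theta) <- nm
    theta
  }

  list(
    n_pars = np, names = nm, pid = pid,
    hyper_idx = hyper_idx,
    ind_by_p = ind_by_p,
    scalar_idx = scalar_idx, blockpar_idx = blockpar_idx,
    n_like_blocks = if (offset_model) 1L else nb,
    lp_hyper = lp_hyper, lp_ind = lp_ind, lp_like = lp_like,
    lp_like_block = lp_like_block,
    total = total, init_draw = init_draw,
    n_participants = length(pid)
  )
}

#' Joint log posterior of a hierarchical model
#'
#' Sum of the hyperprior terms, the truncated-normal individual-level prior
#' terms (conditional on the group level), and the diffusion log likelihood.
#' Returns `-Inf` outside any truncation bound. Deterministic: the same
#' vector always yields the identical value.
#'
#' @param spec A `ddm_model_spec`.
#' @param data A trial table (restricted internally to the spec's blocks).
#' @param theta Flat parameter vector in the spec's packing order.
#' @return A single log-density value.
#' @export
log_posterior <- function(spec, data, theta) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  check_theta(spec, theta)
  lp_components(spec, data)$total(as.numeric(theta))
}
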