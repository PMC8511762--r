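#' Default hierarchical priors
#'
#' Weakly informative priors on the `s = 1` scale, each given as
#' `c(location, scale, lower, upper)` of a (possibly untruncated) normal.
#' Group-level means of the diffusion parameters get truncated normals over
#' their natural domains; all group-level standard deviations share one
#' truncated-normal prior; the distance-from-optimality mean `mu_c` and the
#' group difference `delta_c` get standard normals centred at 0 (a
#' Savage-Dickey test at 0 needs positive prior density there). The
#' truncation bounds double as the domains of the individual-level truncated
#' normals.
#'
#' @return A named list of prior specs; override any element via
#'   [modifyList()]-style `priors` arguments of the spec builders.
#' @export
default_priors <- function() {
  list(
    mu_v = c(2, 2, 0, 10),
    mu_zr = c(0.5, 0.2, 0.2, 0.8),
    mu_ter = c(0.3, 0.3, 0, 1),
    mu_a = c(1.5, 1.5, 0, 6),
    sigma = c(0.5, 0.5, 0, 5),
    mu_c = c(0, 1, -Inf, Inf),
    delta_c = c(0, 1, -Inf, Inf)
  )
}

merge_priors <- function(priors) {
  out <- modifyList(default_priors(), priors %||% list())
  for (nm in names(out)) {
    p <- out[[nm]]
    if (length(p) != 4 || p[2] <= 0 || p[3] >= p[4]) {
      abort(paste0("prior `", nm, "` must be c(loc, scale > 0, lower < upper)"),
            class = "rrddm_config_error")
    }
  }
  out
}

participants_from <- function(x) {
  if (is.data.frame(x) && all(c("participant_id", "group") %in% names(x))) {
    return(dplyr::distinct(tibble::as_tibble(x)[c("participant_id", "group")]))
  }
  abort("need a data frame with participant_id and group columns",
        class = "rrddm_input_error")
}

hyper_row <- function(name, param, group, block, prior) {
  tibble::tibble(name = name, role = "hyper", param = param, group = group,
                 participant = NA_character_, block = block,
                 lower = NA_real_, upper = NA_real_,
                 prior_loc = prior[1], prior_scale = prior[2],
                 prior_lower = prior[3], prior_upper = prior[4],
                 hyper_loc = NA_character_, hyper_scale = NA_character_)
}

ind_row <- function(name, param, group, participant, block, bounds,
                    hyper_loc, hyper_scale) {
  tibble::tibble(name = name, role = "individual", param = param,
                 group = group, participant = participant, block = block,
                 lower = bounds[1], upper = bounds[2],
                 prior_loc = NA_real_, prior_scale = NA_real_,
                 prior_lower = NA_real_, prior_upper = NA_real_,
                 hyper_loc = hyper_loc, hyper_scale = hyper_scale)
}

new_model_spec <- function(model_id, participants, groups, blocks, pars,
                           priors, timing = NULL, s = 1) {
  stopifnot(!anyDuplicated(pars$name))
  structure(
    list(model_id = model_id, participants = participants, groups = groups,
         blocks = blocks, pars = pars, priors = priors, timing = timing,
         s = s),
    class = "ddm_model_spec"
  )
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat(sprintf("<ddm_model_spec> %s: %d participants, %d groups, %d free parameters\n",
              x$model_id, nrow(x$participants), length(x$groups),
              nrow(x$pars)))
  if (!is.null(x$blocks)) {
    cat("  blocks:", paste(range(x$blocks), collapse = "-"), "\n")
  }
  invisible(x)
}

#' Number of free parameters of a model spec
#' @param spec A `ddm_model_spec`.
#' @return Integer count.
#' @export
n_free_parameters <- function(spec) nrow(spec$pars)

block_spec_core <- function(participants, blocks, priors, s, block_drift,
                            model_id) {
  participants <- participants_from(participants)
  if (nrow(participants) < 1) {
    abort("need at least one participant", class = "rrddm_input_error")
  }
  blocks <- sort(unique(as.integer(blocks)))
  pr <- merge_priors(priors)
  groups <- unique(participants$group)
  pars <- list()
  for (g in groups) {
    if (!block_drift) {
      pars[[length(pars) + 1L]] <- dplyr::bind_rows(
        hyper_row(paste0("mu_v[", g, "]"), "mu_v", g, NA_integer_, pr$mu_v),
        hyper_row(paste0("sigma_v[", g, "]"), "sigma_v", g, NA_integer_, pr$sigma)
      )
    }
    pars[[length(pars) + 1L]] <- dplyr::bind_rows(
      hyper_row(paste0("mu_zr[", g, "]"), "mu_zr", g, NA_integer_, pr$mu_zr),
      hyper_row(paste0("sigma_zr[", g, "]"), "sigma_zr", g, NA_integer_, pr$sigma),
      hyper_row(paste0("mu_ter[", g, "]"), "mu_ter", g, NA_integer_, pr$mu_ter),
      hyper_row(paste0("sigma_ter[", g, "]"), "sigma_ter", g, NA_integer_, pr$sigma)
    )
    for (b in blocks) {
      pars[[length(pars) + 1L]] <- dplyr::bind_rows(
        hyper_row(sprintf("mu_a[%s,%d]", g, b), "mu_a", g, b, pr$mu_a),
        hyper_row(sprintf("sigma_a[%s,%d]", g, b), "sigma_a", g, b, pr$sigma)
      )
      if (block_drift) {
        pars[[length(pars) + 1L]] <- dplyr::bind_rows(
          hyper_row(sprintf("mu_v[%s,%d]", g, b), "mu_v", g, b, pr$mu_v),
          hyper_row(sprintf("sigma_v[%s,%d]", g, b), "sigma_v", g, b, pr$sigma)
        )
      }
    }
  }
  for (k in seq_len(nrow(participants))) {
    p <- participants$participant_id[k]
    g <- participants$group[k]
    if (!block_drift) {
      pars[[length(pars) + 1L]] <- ind_row(
        paste0("v[", p, "]"), "v", g, p, NA_integer_, pr$mu_v[3:4],
        paste0("mu_v[", g, "]"), paste0("sigma_v[", g, "]")
      )
    }
    pars[[length(pars) + 1L]] <- dplyr::bind_rows(
      ind_row(paste0("zr[", p, "]"), "zr", g, p, NA_integer_, pr$mu_zr[3:4],
              paste0("mu_zr[", g, "]"), paste0("sigma_zr[", g, "]")),
      ind_row(paste0("ter[", p, "]"), "ter", g, p, NA_integer_, pr$mu_ter[3:4],
              paste0("mu_ter[", g, "]"), paste0("sigma_ter[", g, "]"))
    )
    for (b in blocks) {
      pars[[length(pars) + 1L]] <- ind_row(
        sprintf("a[%s,%d]", p, b), "a", g, p, b, pr$mu_a[3:4],
        sprintf("mu_a[%s,%d]", g, b), sprintf("sigma_a[%s,%d]", g, b)
      )
      if (block_drift) {
        pars[[length(pars) + 1L]] <- ind_row(
          sprintf("v[%s,%d]", p, b), "v", g, p, b, pr$mu_v[3:4],
          sprintf("mu_v[%s,%d]", g, b), sprintf("sigma_v[%s,%d]", g, b)
        )
      }
    }
  }
  new_model_spec(model_id, participants, groups, blocks,
                 dplyr::bind_rows(pars), pr, s = s)
}

#' Block-threshold hierarchical model
#'
#' The qualitative-analysis model: per participant, drift `v_i`, starting
#' point `zr_i`, non-decision time `ter_i`, and one threshold `a_ij` per
#' block — only the threshold varies between blocks. Each group gets a fully
#' separate hierarchy: truncated-normal group levels `(mu, sigma)` for `v`,
#' `zr`, `ter`, and per-block levels `(mu_aj, sigma_aj)` for the thresholds.
#'
#' @param participants A trial table or a tibble with `participant_id` and
#'   `group`.
#' @param blocks Integer block labels to model.
#' @param priors Named list overriding [default_priors()].
#' @param s Diffusion coefficient.
#' @return A `ddm_model_spec`.
#' @export
spec_block_threshold <- function(participants, blocks, priors = NULL, s = 1) {
  block_spec_core(participants, blocks, priors, s, block_drift = FALSE,
                  model_id = "block_threshold")
}

#' Block-threshold-and-drift robustness model
#'
#' Robustness variant of [spec_block_threshold()] in which drift rate also
#' varies across blocks, with its own per-block group levels. With a single
#' block it coincides with the block-threshold model up to naming.
#'
#' @inheritParams spec_block_threshold
#' @return A `ddm_model_spec`.
#' @export
spec_block_threshold_drift <- function(participants, blocks, priors = NULL,
                                       s = 1) {
  block_spec_core(participants, blocks, priors, s, block_drift = TRUE,
                  model_id = "block_threshold_drift")
}

offset_ind_rows <- function(p, g, pr, sigma_c_name, mu_c_name) {
  dplyr::bind_rows(
    ind_row(paste0("v[", p, "]"), "v", g, p, NA_integer_, pr$mu_v[3:4],
            paste0("mu_v[", g, "]"), paste0("sigma_v[", g, "]")),
    ind_row(paste0("ter[", p, "]"), "ter", g, p, NA_integer_, pr$mu_ter[3:4],
            paste0("mu_ter[", g, "]"), paste0("sigma_ter[", g, "]")),
    ind_row(paste0("c[", p, "]"), "c", g, p, NA_integer_, c(-Inf, Inf),
            mu_c_name, sigma_c_name)
  )
}

vter_hyper_rows <- function(g, pr) {
  dplyr::bind_rows(
    hyper_row(paste0("mu_v[", g, "]"), "mu_v", g, NA_integer_, pr$mu_v),
    hyper_row(paste0("sigma_v[", g, "]"), "sigma_v", g, NA_integer_, pr$sigma),
    hyper_row(paste0("mu_ter[", g, "]"), "mu_ter", g, NA_integer_, pr$mu_ter),
    hyper_row(paste0("sigma_ter[", g, "]"), "sigma_ter", g, NA_integer_, pr$sigma)
  )
}

#' Single-group distance-from-optimality model
#'
#' The quantitative model for testing whether one group deviates from
#' reward-rate optimality. Per participant: drift `v_i`, non-decision time
#' `ter_i`, and an additive threshold offset `c_i`; the starting point is
#' fixed at 0.5 (the optimality closed forms assume an unbiased start). The
#' participant's single threshold over the analysis blocks is the
#' deterministic node `a_i = a*(v_i, ter_i, timing) + c_i`, with
#' `c_i ~ Normal(mu_c, sigma_c)`. A positive `mu_c` means the group is too
#' cautious. The likelihood is restricted to the second half of the session
#' (blocks 11-20 by default).
#'
#' @inheritParams spec_block_threshold
#' @param timing A [trial_timing()] used inside the deterministic optimal
#'   threshold node.
#' @param blocks Blocks entering the likelihood.
#' @return A `ddm_model_spec`.
#' @export
spec_optimality_offset <- function(participants, timing = trial_timing(),
                                   blocks = 11:20, priors = NULL, s = 1) {
  participants <- participants_from(participants)
  groups <- unique(participants$group)
  if (length(groups) != 1) {
    abort("optimality-offset model is fit to one group at a time",
          class = "rrddm_spec_error")
  }
  g <- groups
  pr <- merge_priors(priors)
  pars <- list(
    vter_hyper_rows(g, pr),
    hyper_row("mu_c", "mu_c", g, NA_integer_, pr$mu_c),
    hyper_row("sigma_c", "sigma_c", g, NA_integer_, pr$sigma)
  )
  for (p in participants$participant_id) {
    pars[[length(pars) + 1L]] <- offset_ind_rows(p, g, pr, "sigma_c", "mu_c")
  }
  new_model_spec("optimality_offset", participants, g,
                 sort(unique(as.integer(blocks))), dplyr::bind_rows(pars),
                 pr, timing = timing, s = s)
}

#' Two-group optimality-difference model
#'
#' Joint model of both groups for the group-difference hypothesis: each group
#' has the structure of [spec_optimality_offset()] with group-separate
#' `v`/`ter` hierarchies and group-specific `sigma_c`, but the offset means
#' are tied to a shared centre and a difference,
#' `mu_c[fixed_time] = mu_c_bar + delta_c / 2` and
#' `mu_c[fixed_trial] = mu_c_bar - delta_c / 2`, so that
#' `delta_c = mu_c[fixed_time] - mu_c[fixed_trial]` carries a direct prior
#' centred at 0 for the Savage-Dickey ratio.
#'
#' @inheritParams spec_optimality_offset
#' @return A `ddm_model_spec`.
#' @export
spec_group_difference <- function(participants, timing = trial_timing(),
                                  blocks = 11:20, priors = NULL, s = 1) {
  participants <- participants_from(participants)
  groups <- c("fixed_time", "fixed_trial")
  if (!setequal(unique(participants$group), groups)) {
    abort("group-difference model needs exactly the groups fixed_time and fixed_trial",
          class = "rrddm_spec_error")
  }
  pr <- merge_priors(priors)
  pars <- list()
  for (g in groups) pars[[length(pars) + 1L]] <- vter_hyper_rows(g, pr)
  pars[[length(pars) + 1L]] <- dplyr::bind_rows(
    hyper_row("mu_c_bar", "mu_c_bar", NA_character_, NA_integer_, pr$mu_c),
    hyper_row("delta_c", "delta_c", NA_character_, NA_integer_, pr$delta_c),
    hyper_row("sigma_c[fixed_time]", "sigma_c", "fixed_time", NA_integer_, pr$sigma),
    hyper_row("sigma_c[fixed_trial]", "sigma_c", "fixed_trial", NA_integer_, pr$sigma)
  )
  for (k in seq_len(nrow(participants))) {
    p <- participants$participant_id[k]
    g <- participants$group[k]
    pars[[length(pars) + 1L]] <- offset_ind_rows(
      p, g, pr, paste0("sigma_c[", g, "]"), NA_character_
    )
  }
  new_model_spec("group_difference", participants, groups,
                 sort(unique(as.integer(blocks))), dplyr::bind_rows(pars),
                 pr, timing = timing, s = s)
}

#' Serialise a model spec to JSON
#'
#' Used by run manifests and the preregistration renderer.
#' @param spec A `ddm_model_spec`.
#' @return A JSON string.
#' @export
spec_to_json <- function(spec) {
  jsonlite::toJSON(
    list(model_id = spec$model_id,
         groups = spec$groups,
         n_participants = nrow(spec$participants),
         blocks = spec$blocks,
         s = spec$s,
         parameters = spec$pars),
    dataframe = "rows", auto_unbox = TRUE, na = "null", digits = NA
  )
}
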