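# YAML pipeline configuration: sections design / population / priors /
# sampler / exclusions / timing / inference, all optional, each mirroring
# the corresponding constructor's arguments. Schema-validated before any
# compute.

config_sections <- c("design", "population", "priors", "sampler",
                     "exclusions", "timing", "inference")

#' Read and validate a pipeline configuration
#'
#' @param path Path to a YAML file.
#' @return A validated `rrddm_config` (named list of sections).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' Checks section names and materialises each section through its
#' constructor, so schema violations surface before any compute, naming the
#' offending keys.
#'
#' @param cfg A named list as returned by [yaml::read_yaml()].
#' @return The validated `rrddm_config`.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) {
    abort("config must be a mapping of sections", class = "rrddm_config_error")
  }
  unknown <- setdiff(names(cfg), config_sections)
  if (length(unknown)) {
    abort(paste0("unknown config section(s): ",
                 paste(unknown, collapse = ", ")),
          class = "rrddm_config_error")
  }
  check_keys <- function(section, allowed) {
    bad <- setdiff(names(cfg[[section]]), allowed)
    if (length(bad)) {
      abort(paste0("config section `", section, "` has unknown key(s): ",
                   paste(bad, collapse = ", ")),
            class = "rrddm_config_error")
    }
  }
  timing <- trial_timing(cfg$timing$overhead %||% 1.0)
  check_keys("timing", "overhead")
  check_keys("design", c("n_per_group", "n_blocks", "fixed_trials",
                         "fixed_time"))
  check_keys("sampler", c("n_chains", "n_iter", "burn_in", "gamma", "jitter",
                          "migration_prob", "gamma1_prob"))
  check_keys("exclusions", c("drop_first_block", "rt_min", "rt_max",
                             "min_accuracy", "min_eligible_trials"))
  check_keys("population", c("v", "zr", "ter", "a_init", "lambda", "c_offset"))
  check_keys("inference", c("estimator", "blocks"))
  design <- do.call(experiment_design,
                    c(cfg$design %||% list(), list(timing = timing)))
  pop_args <- lapply(cfg$population %||% list(), unlist)
  population <- do.call(group_population, pop_args)
  priors <- merge_priors(lapply(cfg$priors %||% list(), unlist))
  sampler <- do.call(de_config, cfg$sampler %||% list())
  exclusions <- do.call(exclusion_config, cfg$exclusions %||% list())
  structure(
    list(design = design, population = population, priors = priors,
         sampler = sampler, exclusions = exclusions, timing = timing,
         inference = list(
           estimator = cfg$inference$estimator %||% "kde",
           blocks = cfg$inference$blocks %||% 11:20
         ),
         raw = cfg),
    class = "rrddm_config"
  )
}

#' Serialise a configuration back to YAML
#'
#' Writes the raw section values so that parse -> serialise -> parse is the
#' identity.
#'
#' @param cfg An `rrddm_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rrddm_config"))
  yaml::write_yaml(cfg$raw, path)
  invisible(path)
}

#' Run manifest
#'
#' A small provenance record tying pipeline outputs to their configuration:
#' config snapshot, root seed, executed stage order, input/output file
#' hashes, and package version.
#'
#' @param config An `rrddm_config` (or `NULL`).
#' @param seed Root seed of the run.
#' @param stages Character vector of executed stages, in order.
#' @param files Named character vector of file paths to hash.
#' @return A `run_manifest` list; write it with [write_manifest()].
#' @export
run_manifest <- function(config = NULL, seed = NA_integer_,
                         stages = character(), files = character()) {
  hashes <- vapply(files, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, character(1))
  structure(
    list(
      package_version = as.character(utils::packageVersion("rrddm")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      stages = stages,
      files = as.list(hashes),
      config = if (is.null(config)) NULL else config$raw
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Derive a named per-stage seed from a root seed
#'
#' All pipeline randomness flows from one root seed split into named
#' streams, so stages are independently reproducible.
#'
#' @param seed Root integer seed.
#' @param stage Stage name (e.g. `"simulate"`, `"fit"`, `"recover"`).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 104729L, preprocess = 130649L, fit = 15487469L,
               optimality = 32452843L, bayesfactors = 49979687L,
               recover = 67867967L, robustness = 86028121L,
               prereg = 102334155L, report = 122949823L)
  off <- offsets[[stage]] %||% 0L
  as.integer((as.double(seed) * 2654435761 + off) %% 2147483647)
}
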