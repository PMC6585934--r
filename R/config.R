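# Run configuration: a JSON file mirroring the pipeline's knobs.

config_defaults <- function() {
  list(
    scenarios = "base",
    prior = list(style = "vague"),
    mcmc = list(n_chains = 3L, n_iter = 75000L, burn_in = 25000L, thin = 4L,
                init_scale = 1),
    discounts = list(cost_rate = 0.04, effect_rate = 0.015),
    spend_increase = 0.10,
    adjust_mode = "power",
    curve_grid = list(from = 0, to = 2e5, by = 5000),
    verbosity = 1L
  )
}

known_config_keys <- c("panel", "life_inputs", "scenarios", "prior", "mcmc",
                       "discounts", "spend_increase", "adjust_mode",
                       "curve_grid", "output_dir", "seed", "verbosity")

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, fills defaults (protocol settings: 3 chains of
#' 75,000 iterations with 25,000 burn-in and thinning by 4; 4% / 1.5%
#' discounting; a 10% spending increase), and validates. All violations are
#' reported at once. Each of the two inputs (`panel`, `life_inputs`) must
#' carry exactly one of a `path` (delimited tables on disk) or a `synthetic`
#' block (arguments for [true_panel_params()] / [life_surface_params()]).
#' A `seed` is required because every run has at least one stochastic stage.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_kthresh(paste("config file not found:", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config A configuration list (pre-parse form).
#' @export
validate_config <- function(config) {
  bad <- character(0)
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown))
    bad <- c(bad, paste("unknown keys:", paste(unknown, collapse = ", ")))

  cfg <- modifyList(config_defaults(), config)

  for (input in c("panel", "life_inputs")) {
    blk <- cfg[[input]]
    if (is.null(blk)) {
      bad <- c(bad, sprintf("missing required key: %s", input))
    } else {
      has_path <- !is.null(blk$path)
      has_syn <- !is.null(blk$synthetic)
      if (has_path == has_syn)
        bad <- c(bad, sprintf(
          "%s must carry exactly one of 'path' or 'synthetic'", input))
    }
  }
  if (is.null(cfg$seed)) {
    bad <- c(bad, "missing required key: seed (every run has a stochastic stage)")
  } else if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    bad <- c(bad, "seed must be an integer")
  }
  if (is.null(cfg$output_dir))
    bad <- c(bad, "missing required key: output_dir")
  unknown_sc <- setdiff(unlist(cfg$scenarios), scenario_labels)
  if (length(unknown_sc))
    bad <- c(bad, paste("unknown scenario label(s):",
                        paste(unknown_sc, collapse = ", ")))
  m <- cfg$mcmc
  if (!is.null(m$burn_in) && !is.null(m$n_iter) && m$burn_in >= m$n_iter)
    bad <- c(bad, "mcmc: burn_in must be < n_iter")
  if (!is.null(m$thin) && m$thin < 1) bad <- c(bad, "mcmc: thin must be >= 1")
  if (!is.null(m$n_chains) && m$n_chains < 1)
    bad <- c(bad, "mcmc: n_chains must be >= 1")
  d <- cfg$discounts
  if (any(unlist(d) < 0)) bad <- c(bad, "discounts: rates must be >= 0")
  if (!is.null(cfg$spend_increase) && cfg$spend_increase <= -1)
    bad <- c(bad, "spend_increase must exceed -1")
  if (!cfg$adjust_mode %in% c("power", "linear"))
    bad <- c(bad, "adjust_mode must be 'power' or 'linear'")
  if (!is.null(cfg$prior$style) &&
      !cfg$prior$style %in% c("vague", "elasticity_interval"))
    bad <- c(bad, "prior style must be 'vague' or 'elasticity_interval'")

  if (length(bad))
    stop_kthresh(paste0("invalid configuration:\n  - ",
                        paste(bad, collapse = "\n  - ")))
  cfg$scenarios <- unlist(cfg$scenarios)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as JSON
#'
#' Round-trips with [load_config()].
#'
#' @param config A `run_config` (or plain list).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
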