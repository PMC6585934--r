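# End-to-end pipeline: simulate -> fit -> diagnose -> translate -> report.

log_msg <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1L) > 0) message(sprintf(...))
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_kthresh(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages up to and including the requested one
#' (`simulate < fit < translate < report`; `"all"` = `"report"`), writing all
#' artifacts as delimited text under `config$output_dir`: the (possibly
#' synthetic) panel and life inputs, per-scenario posterior draws and
#' convergence diagnostics, the scenario report and threshold summaries,
#' probability-below-value curves, and a reproducibility manifest (seed,
#' settings, MD5 content digests). Every file regenerates byte-identically
#' under a fixed seed and configuration. Any stage error aborts with the
#' stage name in the message.
#'
#' @param config A `run_config` from [load_config()] / [validate_config()].
#' @param stages `"all"`, `"simulate"`, `"fit"`, `"translate"` or `"report"`.
#' @return Invisibly, a list with the artifact paths and (when run) the
#'   scenario report.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stages <- match.arg(stages, c("all", "simulate", "fit", "translate",
                                "report"))
  rank <- c(simulate = 1, fit = 2, translate = 3, report = 4, all = 4)
  upto <- rank[[stages]]
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    log_msg(config, "[kthresh] stage %s done (%.1fs elapsed)", stage,
            proc.time()[["elapsed"]] - t0)
  }

  # --- simulate / load inputs -----------------------------------------
  panel <- life <- NULL
  stage_guard("simulate", {
    if (!is.null(config$panel$synthetic)) {
      args <- config$panel$synthetic
      args$seed <- args$seed %||% config$seed
      sim <- generate_panel(do.call(true_panel_params, args))
      panel <- sim$panel
      write_panel(sim, file.path(out, "panel.csv"))
      artifacts <- c(artifacts, file.path(out, "panel.csv"))
    } else {
      panel <- read_panel(config$panel$path)
    }
    if (!is.null(config$life_inputs$synthetic)) {
      life <- generate_life_inputs(
        do.call(life_surface_params, config$life_inputs$synthetic))
      write_life_inputs(life, file.path(out, "life_inputs"))
      artifacts <- c(artifacts, file.path(out, "life_inputs"))
    } else {
      life <- read_life_inputs(config$life_inputs$path)
    }
  })
  tick("simulate")
  if (upto < 2) return(invisible(list(artifacts = artifacts)))

  # --- fit + diagnose --------------------------------------------------
  mc <- config$mcmc
  mcfg <- mcmc_config(n_chains = mc$n_chains, n_iter = mc$n_iter,
                      burn_in = mc$burn_in, thin = mc$thin,
                      seed = config$seed, init_scale = mc$init_scale %||% 1)
  discounts <- discount_spec(config$discounts$cost_rate,
                             config$discounts$effect_rate)
  scen <- stage_guard("fit", {
    run_scenarios(panel, life, battery = config$scenarios, config = mcfg,
                  discounts = discounts,
                  spend_increase = config$spend_increase,
                  mode = config$adjust_mode)
  })
  stage_guard("fit", {
    for (sc in names(scen$fits)) {
      fit <- scen$fits[[sc]]
      if (inherits(fit, "mcmc_fit")) {
        write_draws(fit, file.path(out, sprintf("draws_%s.csv", sc)))
        artifacts <- c(artifacts, file.path(out, sprintf("draws_%s.csv", sc)))
        dg <- diagnose(fit$draws)
        write.csv(dg$summary,
                  file.path(out, sprintf("diagnostics_%s.csv", sc)),
                  row.names = FALSE, quote = FALSE)
        artifacts <- c(artifacts,
                       file.path(out, sprintf("diagnostics_%s.csv", sc)))
        for (f in fit$flags) log_msg(config, "[kthresh] %s: warning: %s", sc, f)
      }
    }
  })
  tick("fit")
  if (upto < 3) {
    return(invisible(list(artifacts = artifacts, scenarios = scen)))
  }

  # --- translate -------------------------------------------------------
  stage_guard("translate", {
    meta <- list(seed = config$seed, spend_increase = config$spend_increase,
                 cost_rate = config$discounts$cost_rate,
                 effect_rate = config$discounts$effect_rate,
                 adjust_mode = config$adjust_mode)
    for (sc in names(scen$summaries)) {
      ts <- scen$summaries[[sc]]
      d <- new_scenario_delta(mean(ts$deltas[, "delta_cost"]),
                              mean(ts$deltas[, "delta_qaly"]),
                              mean(ts$deltas[, "delta_ly"]),
                              elasticity_used = mean(ts$elasticities))
      write_delta(d, file.path(out, sprintf("delta_%s.csv", sc)),
                  meta = c(meta, scenario = sc))
      artifacts <- c(artifacts, file.path(out, sprintf("delta_%s.csv", sc)))
    }
  })
  tick("translate")
  if (upto < 4) {
    return(invisible(list(artifacts = artifacts, scenarios = scen)))
  }

  # --- report ----------------------------------------------------------
  stage_guard("report", {
    write.csv(scen$report, file.path(out, "report.csv"), row.names = FALSE,
              quote = FALSE)
    jsonlite::write_json(scen$report, file.path(out, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    grid <- seq(config$curve_grid$from, config$curve_grid$to,
                by = config$curve_grid$by)
    for (sc in names(scen$fits)) {
      e <- scen$summaries[[sc]]$elasticities
      curve <- probability_below(e, life,
                                 spend_increase = config$spend_increase,
                                 discounts = discounts, grid = grid,
                                 mode = config$adjust_mode)
      write_curve(curve, file.path(out, sprintf("curve_%s.csv", sc)),
                  meta = list(scenario = sc, seed = config$seed))
      artifacts <- c(artifacts, file.path(out, sprintf("curve_%s.csv", sc)))
    }
    artifacts <- c(artifacts, file.path(out, "report.csv"),
                   file.path(out, "report.json"))
    files <- setdiff(artifacts, file.path(out, "life_inputs"))
    digests <- tools::md5sum(files[file.exists(files)])
    manifest <- list(seed = config$seed,
                     settings = unclass(config)[setdiff(names(config),
                                                        c("output_dir"))],
                     digests = as.list(digests))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out, "manifest.json"))
  })
  tick("report")
  invisible(list(artifacts = artifacts, scenarios = scen,
                 report = scen$report))
}
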