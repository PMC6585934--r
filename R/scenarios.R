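# Scenario battery: the base case and the sensitivity analyses.

scenario_labels <- c("base", "prior_gallet", "prior_claxton",
                     "years_2001_2010", "frequentist", "no_lag")

#' Run the scenario battery
#'
#' Produces a report table with one row per scenario: posterior mean and
#' equal-tailed 95% interval of the instantaneous coefficient, the lagged
#' coefficient and their sum, and the cost per QALY and per life year with
#' their intervals (ratio evaluated at the elasticity quantiles).
#'
#' Scenarios: `base` (vague priors), `prior_gallet` (informative prior on the
#' instantaneous elasticity centred at -0.13 with 95% interval -0.20/-0.06,
#' meta-analytic total-spending evidence), `prior_claxton` (centred at -1.43,
#' interval -1.86/-1.00, an English circulatory-spending estimate),
#' `years_2001_2010` (vague priors, activity-based-financing years only),
#' `frequentist` (OLS with year and stratum dummies; the translation step
#' draws 10,000 multivariate-normal coefficient samples), and `no_lag`
#' (lagged spending excluded; the elasticity is the instantaneous
#' coefficient alone and the lagged column is reported as `NA`).
#'
#' @param panel A panel data frame.
#' @param inputs A [life_table_inputs()].
#' @param battery Character vector of scenario labels.
#' @param config An [mcmc_config()].
#' @param discounts A [discount_spec()].
#' @param spend_increase Proportional spending increase (default 0.10).
#' @param mode Mortality-adjustment convention.
#' @param n_freq_draws Coefficient samples for the frequentist translation.
#' @return An object of class `scenario_report`: `report` (data frame),
#'   `summaries` (per-scenario `threshold_summary`), `fits`.
#' @export
run_scenarios <- function(panel, inputs, battery = "base",
                          config = mcmc_config(),
                          discounts = discount_spec(),
                          spend_increase = 0.10,
                          mode = c("power", "linear"),
                          n_freq_draws = 10000L) {
  mode <- match.arg(mode)
  unknown <- setdiff(battery, scenario_labels)
  if (length(unknown))
    stop_kthresh(paste("unknown scenario label(s):",
                       paste(unknown, collapse = ", ")))

  q95 <- function(x) quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  rows <- list(); summaries <- list(); fits <- list()

  for (sc in battery) {
    year_min <- if (sc == "years_2001_2010") 2001 else NULL
    year_max <- if (sc == "years_2001_2010") 2010 else NULL
    frame <- build_model_frame(panel, year_min = year_min,
                               year_max = year_max)
    if (sc == "frequentist") {
      fit <- fit_frequentist(frame, include_lag = TRUE)
      dr <- sample_frequentist(fit, n = n_freq_draws, seed = config$seed)
      alpha <- dr$alpha; beta <- dr$beta; elas <- dr$elasticity
    } else {
      priors <- switch(sc,
        prior_gallet = make_prior("elasticity_interval", mean = -0.13,
                                  ci95 = c(-0.20, -0.06)),
        prior_claxton = make_prior("elasticity_interval", mean = -1.43,
                                   ci95 = c(-1.86, -1.00)),
        make_prior("vague"))
      fit <- fit_mcmc(frame, priors, config,
                      include_lag = (sc != "no_lag"), diagnostics = FALSE)
      alpha <- fit$draws$alpha
      beta <- if (sc == "no_lag") NULL else fit$draws$beta
      elas <- elasticity_draws(fit)
    }
    ts <- summarize_threshold(elas, inputs, spend_increase, discounts, mode)
    rows[[sc]] <- data.frame(
      scenario = sc,
      alpha_mean = mean(alpha), alpha_lo = q95(alpha)[1],
      alpha_hi = q95(alpha)[2],
      beta_mean = if (is.null(beta)) NA_real_ else mean(beta),
      beta_lo = if (is.null(beta)) NA_real_ else q95(beta)[1],
      beta_hi = if (is.null(beta)) NA_real_ else q95(beta)[2],
      elasticity_mean = mean(elas),
      elasticity_lo = q95(elas)[1], elasticity_hi = q95(elas)[2],
      cost_per_qaly = ts$cost_per_qaly,
      cost_per_qaly_lo = ts$ci95_qaly[1], cost_per_qaly_hi = ts$ci95_qaly[2],
      cost_per_ly = ts$cost_per_ly,
      cost_per_ly_lo = ts$ci95_ly[1], cost_per_ly_hi = ts$ci95_ly[2],
      stringsAsFactors = FALSE
    )
    summaries[[sc]] <- ts
    fits[[sc]] <- fit
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, summaries = summaries, fits = fits),
            class = "scenario_report")
}

#' Format a scenario report for display
#'
#' Coefficients to three decimals; currency amounts rounded to the nearest
#' 100 (display only — raw values stay in `$report`).
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @return A data frame of formatted strings.
#' @export
format.scenario_report <- function(x, ...) {
  r <- x$report
  co <- function(m, lo, hi)
    ifelse(is.na(m), "NA",
           sprintf("%.3f (%.3f/%.3f)", m, lo, hi))
  cu <- function(m, lo, hi)
    ifelse(is.na(m), "NA",
           sprintf("%s (%s/%s)",
                   format(round(m / 100) * 100, big.mark = ",", trim = TRUE),
                   format(round(lo / 100) * 100, big.mark = ",", trim = TRUE),
                   format(round(hi / 100) * 100, big.mark = ",", trim = TRUE)))
  data.frame(
    scenario = r$scenario,
    alpha = co(r$alpha_mean, r$alpha_lo, r$alpha_hi),
    beta = co(r$beta_mean, r$beta_lo, r$beta_hi),
    elasticity = co(r$elasticity_mean, r$elasticity_lo, r$elasticity_hi),
    cost_per_qaly = cu(r$cost_per_qaly, r$cost_per_qaly_lo,
                       r$cost_per_qaly_hi),
    cost_per_ly = cu(r$cost_per_ly, r$cost_per_ly_lo, r$cost_per_ly_hi),
    stringsAsFactors = FALSE
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  print(format(x))
  invisible(x)
}
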