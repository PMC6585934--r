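# Incremental costs and effects between two spending/mortality states.

new_scenario_delta <- function(delta_cost, delta_qaly, delta_ly,
                               elasticity_used = NA_real_, detail = NULL) {
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 delta_ly = delta_ly, elasticity_used = elasticity_used,
                 detail = detail),
            class = "scenario_delta")
}

# A closure evaluating the population-weighted incremental discounted cost,
# QALYs and life years of a proportional cardiovascular spending increase,
# as a function of the elasticity draw. Baseline projections and cohort
# preparations are computed once, so evaluating thousands of posterior draws
# is cheap.
make_delta_fn <- function(inputs, spend_increase = 0.10,
                          discounts = discount_spec(),
                          mode = c("power", "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(inputs, "life_table_inputs"))
  pop <- inputs$population
  if (sum(pop$population) <= 0)
    stop_kthresh("total population weight must be positive")
  w <- pop$population / sum(pop$population)
  preps <- lapply(seq_len(nrow(pop)), function(i)
    prepare_cohort(inputs, pop$start_age[i], pop$gender[i]))
  base <- lapply(preps, project_prepared, discounts = discounts)
  mult <- 1 + spend_increase
  function(elasticity) {
    dc <- dq <- dl <- 0
    for (i in seq_along(preps)) {
      alt <- project_prepared(
        preps[[i]], discounts,
        cvd = adjust_mortality(preps[[i]]$cvd, mult, elasticity, mode),
        spend = preps[[i]]$spend * mult)
      dc <- dc + w[i] * (alt$total_cost - base[[i]]$total_cost)
      dq <- dq + w[i] * (alt$qaly - base[[i]]$qaly)
      dl <- dl + w[i] * (alt$ly - base[[i]]$ly)
    }
    c(delta_cost = dc, delta_qaly = dq, delta_ly = dl)
  }
}

#' Incremental costs and effects of a marginal spending increase
#'
#' Projects every starting cohort (age group x gender, weighted by
#' population) under baseline inputs and under an alternative in which
#' per-capita cardiovascular spending is raised by `spend_increase` and
#' cardiovascular mortality is adjusted through [adjust_mortality()] with the
#' given elasticity. Unrelated hospital costs accrued in added life years are
#' part of the incremental cost. Deltas are population-weighted per-capita
#' values (the weighting cancels in any cost-per-QALY ratio).
#'
#' @param inputs A [life_table_inputs()].
#' @param elasticity Spending elasticity of mortality (<= 0 for a protective
#'   effect).
#' @param spend_increase Proportional spending increase (default 0.10).
#' @param discounts A [discount_spec()].
#' @param mode Mortality-adjustment convention, see [adjust_mortality()].
#' @return An object of class `scenario_delta` with `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `elasticity_used`.
#' @export
scenario_delta <- function(inputs, elasticity, spend_increase = 0.10,
                           discounts = discount_spec(),
                           mode = c("power", "linear")) {
  f <- make_delta_fn(inputs, spend_increase, discounts, mode)
  d <- f(elasticity)
  new_scenario_delta(d[["delta_cost"]], d[["delta_qaly"]], d[["delta_ly"]],
                     elasticity_used = elasticity)
}

#' Incremental costs and effects between two observed states
#'
#' Generalizes [scenario_delta()] to two arbitrary input states on the same
#' age/gender grid (for instance, an early and a late observation year):
#' every starting cohort is projected under both, and population-weighted
#' (baseline weights) differences alternative minus baseline are returned.
#'
#' @param inputs_baseline,inputs_alternative [life_table_inputs()] on the
#'   same grid (ages, genders, starting groups, closure age).
#' @param discounts A [discount_spec()].
#' @return A `scenario_delta` (with `elasticity_used = NA`).
#' @export
compare_states <- function(inputs_baseline, inputs_alternative,
                           discounts = discount_spec()) {
  stopifnot(inherits(inputs_baseline, "life_table_inputs"),
            inherits(inputs_alternative, "life_table_inputs"))
  pb <- inputs_baseline$population
  pa <- inputs_alternative$population
  same <- identical(pb[c("age_group", "gender", "start_age")],
                    pa[c("age_group", "gender", "start_age")]) &&
    inputs_baseline$closure_age == inputs_alternative$closure_age &&
    setequal(unique(inputs_baseline$rates$age),
             unique(inputs_alternative$rates$age))
  if (!same)
    stop_kthresh("grid mismatch: both states must share age groups, genders, ages and closure age")
  w <- pb$population / sum(pb$population)
  dc <- dq <- dl <- 0
  for (i in seq_len(nrow(pb))) {
    b <- project_prepared(
      prepare_cohort(inputs_baseline, pb$start_age[i], pb$gender[i]),
      discounts)
    a <- project_prepared(
      prepare_cohort(inputs_alternative, pa$start_age[i], pa$gender[i]),
      discounts)
    dc <- dc + w[i] * (a$total_cost - b$total_cost)
    dq <- dq + w[i] * (a$qaly - b$qaly)
    dl <- dl + w[i] * (a$ly - b$ly)
  }
  new_scenario_delta(dc, dq, dl)
}

#' Write a scenario delta as a delimited table with a metadata header
#'
#' @param delta A `scenario_delta`.
#' @param path Output path.
#' @param meta Named list written as `# key: value` comment lines above the
#'   header (e.g. discount rates, conventions).
#' @return The path, invisibly.
#' @export
write_delta <- function(delta, path, meta = list()) {
  stopifnot(inherits(delta, "scenario_delta"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  df <- data.frame(delta_cost = delta$delta_cost,
                   delta_qaly = delta$delta_qaly,
                   delta_ly = delta$delta_ly,
                   elasticity_used = delta$elasticity_used)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
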