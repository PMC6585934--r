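# Container and I/O for life-table inputs.

#' Life-table inputs
#'
#' Validating constructor for the inputs of the cohort projection: per
#' (age, gender) cardiovascular and other-cause mortality rates and
#' per-capita cardiovascular spending; per (age, gender, time-to-death)
#' quality of life and unrelated hospital cost; population weights per
#' starting age group; and the closure age at which all remaining survivors
#' die. Time-to-death surfaces carry columns for 0 .. H years to death, where
#' the last column is the "background" used for H or more years to death.
#'
#' @param rates Data frame: age, gender, cvd_mortality, other_mortality,
#'   cvd_spending. Single ages must cover every starting age up to
#'   `closure_age` without gaps, per gender.
#' @param qol Data frame: age, gender, ttd, qol (utility in \[0,1\]).
#' @param unrelated Data frame: age, gender, ttd, cost (>= 0).
#' @param population Data frame: age_group, gender, start_age, population.
#' @param closure_age Last age modelled.
#' @return An object of class `life_table_inputs`.
#' @export
life_table_inputs <- function(rates, qol, unrelated, population, closure_age) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_kthresh(sprintf("%s table is missing columns: %s", what,
                           paste(miss, collapse = ", ")))
  }
  need(rates, c("age", "gender", "cvd_mortality", "other_mortality",
                "cvd_spending"), "rates")
  need(qol, c("age", "gender", "ttd", "qol"), "qol")
  need(unrelated, c("age", "gender", "ttd", "cost"), "unrelated")
  need(population, c("age_group", "gender", "start_age", "population"),
       "population")

  if (any(rates$cvd_mortality < 0, na.rm = TRUE) ||
      any(rates$other_mortality < 0, na.rm = TRUE) ||
      any(rates$cvd_spending < 0, na.rm = TRUE))
    stop_kthresh("rates and spending must be >= 0")
  if (any(qol$qol < 0 | qol$qol > 1, na.rm = TRUE))
    stop_kthresh("qol values must lie in [0, 1]")
  if (any(unrelated$cost < 0, na.rm = TRUE))
    stop_kthresh("unrelated costs must be >= 0")
  if (any(population$population < 0))
    stop_kthresh("population must be >= 0")
  if (closure_age < max(population$start_age))
    stop_kthresh("closure_age must be >= every starting age")

  horizon <- max(qol$ttd)
  if (!setequal(unique(qol$ttd), 0:horizon))
    stop_kthresh("qol table must carry consecutive ttd columns 0..H")
  if (!setequal(unique(unrelated$ttd), 0:max(unrelated$ttd)))
    stop_kthresh("unrelated table must carry consecutive ttd columns 0..H")

  for (g in unique(population$gender)) {
    ages <- sort(unique(rates$age[rates$gender == g]))
    span <- seq(min(population$start_age[population$gender == g]), closure_age)
    if (!all(span %in% ages))
      stop_kthresh(sprintf(
        "rates for gender %s must cover ages %d..%d without gaps",
        g, min(span), closure_age))
  }

  structure(list(rates = rates, qol = qol, unrelated = unrelated,
                 population = population,
                 closure_age = as.integer(closure_age),
                 ttd_horizon = as.integer(horizon)),
            class = "life_table_inputs")
}

#' Read / write life-table inputs as delimited text
#'
#' Four headered CSV tables in a directory (`rates.csv`, `qol.csv`,
#' `unrelated.csv`, `population.csv`) plus a small `meta.csv` carrying the
#' closure age.
#'
#' @param inputs A `life_table_inputs` object.
#' @param dir Directory to write to / read from.
#' @return `write_life_inputs` the directory invisibly; `read_life_inputs`
#'   a validated `life_table_inputs`.
#' @export
write_life_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "life_table_inputs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(inputs$rates, file.path(dir, "rates.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(inputs$qol, file.path(dir, "qol.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(inputs$unrelated, file.path(dir, "unrelated.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(inputs$population, file.path(dir, "population.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(key = "closure_age", value = inputs$closure_age),
            file.path(dir, "meta.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_life_inputs
#' @export
read_life_inputs <- function(dir) {
  meta <- read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  life_table_inputs(
    rates = read.csv(file.path(dir, "rates.csv"), stringsAsFactors = FALSE),
    qol = read.csv(file.path(dir, "qol.csv"), stringsAsFactors = FALSE),
    unrelated = read.csv(file.path(dir, "unrelated.csv"),
                         stringsAsFactors = FALSE),
    population = read.csv(file.path(dir, "population.csv"),
                          stringsAsFactors = FALSE),
    closure_age = as.integer(meta$value[meta$key == "closure_age"])
  )
}

#' Discounting specification
#'
#' Annual discount rates for costs and health effects. Year 0 of a
#' projection is undiscounted; year y is discounted by `1/(1+rate)^y`.
#' Defaults follow the Dutch guideline convention of 4% for costs and 1.5%
#' for effects.
#'
#' @param cost_rate Annual discount rate for costs (>= 0).
#' @param effect_rate Annual discount rate for QALYs and life years (>= 0).
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(cost_rate = 0.04, effect_rate = 0.015) {
  if (cost_rate < 0 || effect_rate < 0)
    stop_kthresh("discount rates must be >= 0")
  structure(list(cost_rate = cost_rate, effect_rate = effect_rate),
            class = "discount_spec")
}
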