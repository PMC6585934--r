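# Cohort life-table projection.
#
# Annual cycle from a starting age to the closure age. The probability of
# dying within a year is 1 - exp(-(cvd_rate + other_rate)) (additive
# cause-specific hazards); everyone still alive at the closure age dies
# there. A person lives the whole year in which they die, so the probability
# of living year y (fully) is the probability of surviving to its start.
# Quality of life and unrelated hospital costs depend on current age and on
# time to death, truncated at the surface horizon H: H or more years from
# death takes the background column. Year 0 is undiscounted.

#' Adjust a cause-specific mortality rate for a spending change
#'
#' Default (`mode = "power"`) is the constant-elasticity convention implied
#' by a log-log regression: the rate is multiplied by
#' `spend_multiplier^elasticity`. The alternative literal linear reading
#' multiplies the rate by `1 + 0.9 * elasticity * (spend_multiplier - 1)`
#' and errors if that factor is negative.
#'
#' @param cvd_mortality Rate(s) per person-year (>= 0); vectorized.
#' @param spend_multiplier Spending ratio alternative/baseline (> 0).
#' @param elasticity Spending elasticity of mortality (dimensionless).
#' @param mode `"power"` (default) or `"linear"`.
#' @return Adjusted rate(s).
#' @examples
#' adjust_mortality(0.02, 1.1, -0.19)  # 0.02 * 1.1^-0.19 = 0.0196411
#' @export
adjust_mortality <- function(cvd_mortality, spend_multiplier, elasticity,
                             mode = c("power", "linear")) {
  mode <- match.arg(mode)
  if (any(cvd_mortality < 0)) stop_kthresh("cvd_mortality must be >= 0")
  if (any(spend_multiplier <= 0)) stop_kthresh("spend_multiplier must be > 0")
  if (mode == "power") {
    cvd_mortality * spend_multiplier^elasticity
  } else {
    f <- 1 + 0.9 * elasticity * (spend_multiplier - 1)
    if (any(f < 0))
      stop_kthresh("linear mortality adjustment would turn a rate negative")
    cvd_mortality * f
  }
}

# Precompute everything about one starting cohort that does not depend on
# the elasticity draw: rate/spending vectors by age, the (year-lived, year-
# of-death) pair expansion, and the qol / unrelated-cost values on it.
prepare_cohort <- function(inputs, start_age, gender) {
  stopifnot(inherits(inputs, "life_table_inputs"))
  ages <- seq(start_age, inputs$closure_age)
  N <- length(ages)
  H <- inputs$ttd_horizon

  r <- inputs$rates[inputs$rates$gender == gender, , drop = FALSE]
  idx <- match(ages, r$age)
  if (anyNA(idx))
    stop_kthresh(sprintf("missing rates for age %d, gender %s",
                         ages[which(is.na(idx))[1]], gender))
  cvd <- r$cvd_mortality[idx]
  other <- r$other_mortality[idx]
  spend <- r$cvd_spending[idx]

  lookup_surface <- function(df, value_col, what) {
    key <- paste(df$age, df$ttd, sep = "|")
    m <- matrix(NA_real_, N, H + 1L)
    want <- expand.grid(age = ages, ttd = 0:H)
    pos <- match(paste(want$age, want$ttd, sep = "|"),
                 key[df$gender == gender])
    vals <- df[[value_col]][df$gender == gender][pos]
    if (anyNA(vals)) {
      b <- which(is.na(vals))[1]
      stop_kthresh(sprintf("missing %s cell at (age %d, ttd %d), gender %s",
                           what, want$age[b], want$ttd[b], gender))
    }
    m[] <- vals
    m
  }
  Q <- lookup_surface(inputs$qol, "qol", "quality-of-life")
  U <- lookup_surface(inputs$unrelated, "cost", "unrelated-cost")

  # all (year lived y, year of death d >= y) pairs, 1-based
  dd <- sequence(N:1) + rep(seq_len(N), N:1) - 1L
  yy <- rep(seq_len(N), N:1)
  ttd <- pmin(dd - yy, H)
  qv <- Q[cbind(yy, ttd + 1L)]
  uv <- U[cbind(yy, ttd + 1L)]

  list(ages = ages, N = N, cvd = cvd, other = other, spend = spend,
       yy = yy, dd = dd, qv = qv, uv = uv,
       start_age = start_age, gender = gender)
}

# Core projection on a prepared cohort; returns survival, death distribution
# and discounted totals.
project_prepared <- function(prep, discounts, cvd = NULL, spend = NULL) {
  cvd <- cvd %||% prep$cvd
  spend <- spend %||% prep$spend
  N <- prep$N
  q <- 1 - exp(-(cvd + prep$other))
  q[N] <- 1                             # closure: everyone dies
  S <- c(1, cumprod(1 - q))[seq_len(N)] # P(alive at start of year y)
  Pd <- S * q                           # P(death in year y)
  disc_e <- (1 + discounts$effect_rate)^-(seq_len(N) - 1)
  disc_c <- (1 + discounts$cost_rate)^-(seq_len(N) - 1)
  w <- Pd[prep$dd]                      # P(death year d), per (y, d) pair
  qaly <- sum(disc_e[prep$yy] * w * prep$qv)
  ly <- sum(disc_e * S)
  cvd_cost <- sum(disc_c * S * spend)
  unrelated_cost <- sum(disc_c[prep$yy] * w * prep$uv)
  list(q = q, S = S, Pd = Pd,
       qaly = qaly, ly = ly, cvd_cost = cvd_cost,
       unrelated_cost = unrelated_cost,
       total_cost = cvd_cost + unrelated_cost)
}

#' Project one cohort through the life table
#'
#' @param inputs A [life_table_inputs()].
#' @param start_age First (single) age of the cohort.
#' @param gender Gender label present in the inputs.
#' @param discounts A [discount_spec()].
#' @param cvd_mortality_override Optional vector of cardiovascular rates per
#'   age (start to closure) replacing the inputs' rates.
#' @param cvd_spending_override Optional vector of per-capita cardiovascular
#'   spending per age replacing the inputs' values.
#' @return An object of class `cohort_projection`: `table` (per projection
#'   year: age, death probability of the year, survival to the year's start,
#'   probability of dying in the year) and `totals` (discounted QALYs, life
#'   years, cardiovascular cost, unrelated cost).
#' @export
project_cohort <- function(inputs, start_age, gender,
                           discounts = discount_spec(),
                           cvd_mortality_override = NULL,
                           cvd_spending_override = NULL) {
  prep <- prepare_cohort(inputs, start_age, gender)
  if (!is.null(cvd_mortality_override) &&
      length(cvd_mortality_override) != prep$N)
    stop_kthresh(sprintf("cvd_mortality_override must have length %d", prep$N))
  if (!is.null(cvd_spending_override) &&
      length(cvd_spending_override) != prep$N)
    stop_kthresh(sprintf("cvd_spending_override must have length %d", prep$N))
  pr <- project_prepared(prep, discounts,
                         cvd = cvd_mortality_override,
                         spend = cvd_spending_override)
  structure(list(
    table = data.frame(age = prep$ages, survival = pr$S,
                       death_prob = pr$Pd),
    totals = list(qaly = pr$qaly, life_years = pr$ly,
                  cvd_cost = pr$cvd_cost,
                  unrelated_cost = pr$unrelated_cost,
                  total_cost = pr$total_cost),
    start_age = start_age, gender = gender, discounts = discounts
  ), class = "cohort_projection")
}
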