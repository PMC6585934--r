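# Synthetic life-table input surfaces.
#
# Stand-ins for the registry-derived inputs of the translation step: cause
# partitioned mortality (cardiovascular vs all other causes), per-capita
# cardiovascular hospital spending by age, a quality-of-life surface over
# (age, time to death), an unrelated-hospital-cost surface over (age, time to
# death), and population weights per starting age group. All values are
# parametric; none are copied from published tables.

#' Parameters of the synthetic life-table surfaces
#'
#' @param gompertz_a,gompertz_b Other-cause mortality rate `a * exp(b * age)`.
#' @param cvd_a,cvd_b Cardiovascular mortality rate, same parametric form.
#' @param qol_at_min_age Quality of life at `min_age` far from death.
#' @param qol_age_slope Linear decline of quality of life per year of age.
#' @param qol_ttd_decrements Additive quality-of-life losses for the last
#'   years before death, ordered from the death year outward: element 1
#'   applies when time to death is 0, element 2 when it is 1, and so on.
#'   Ages at least `length(qol_ttd_decrements)` years from death take no
#'   decrement (the "background" column).
#' @param cvd_spending_peak Per-capita cardiovascular hospital spending at the
#'   peak age (currency/person/year).
#' @param cvd_spending_peak_age,cvd_spending_width Location and width of the
#'   spending-by-age bump.
#' @param unrelated_cost_base Annual non-cardiovascular hospital cost at
#'   `min_age` (background, i.e. far from death).
#' @param unrelated_cost_age_slope Log-linear growth of that cost per year of
#'   age.
#' @param unrelated_cost_terminal Multiplier on the unrelated cost in the last
#'   year of life (time to death 0).
#' @param population_by_stratum Persons per starting age group x gender cell;
#'   recycled over the grid (age group fastest). Defaults to a population
#'   thinning out with age.
#' @param age_groups,genders Starting-cohort grid (matching the panel's).
#' @param closure_age Last single age modelled; everyone alive there dies.
#'
#' @return An object of class `life_surface_params`.
#' @export
life_surface_params <- function(gompertz_a = 2e-5,
                                gompertz_b = 0.10,
                                cvd_a = 4e-6,
                                cvd_b = 0.11,
                                qol_at_min_age = 0.87,
                                qol_age_slope = 0.004,
                                qol_ttd_decrements = c(0.25, 0.12, 0.07,
                                                       0.04, 0.02),
                                cvd_spending_peak = 1000,
                                cvd_spending_peak_age = 80,
                                cvd_spending_width = 18,
                                unrelated_cost_base = 900,
                                unrelated_cost_age_slope = 0.03,
                                unrelated_cost_terminal = 6,
                                population_by_stratum = NULL,
                                age_groups = c("60-64", "65-69", "70-74",
                                               "75-79", "80-84", "85-89",
                                               "90-94", "95+"),
                                genders = c("male", "female"),
                                closure_age = 105L) {
  starts <- age_group_start(age_groups)
  if (is.null(population_by_stratum)) {
    population_by_stratum <- as.vector(outer(
      round(5e5 * exp(-0.09 * (starts - min(starts)))), c(0.9, 1.1)))
  }
  n <- length(age_groups) * length(genders)
  population_by_stratum <- rep_len(population_by_stratum, n)
  if (any(population_by_stratum < 0))
    stop_kthresh("population_by_stratum must be >= 0")
  if (any(c(gompertz_a, cvd_a, cvd_spending_peak, unrelated_cost_base,
            unrelated_cost_terminal) < 0))
    stop_kthresh("rate and cost parameters must be >= 0")
  if (closure_age < max(starts))
    stop_kthresh("closure_age must be at least the largest starting age")
  structure(list(
    gompertz_a = gompertz_a, gompertz_b = gompertz_b,
    cvd_a = cvd_a, cvd_b = cvd_b,
    qol_at_min_age = qol_at_min_age, qol_age_slope = qol_age_slope,
    qol_ttd_decrements = qol_ttd_decrements,
    cvd_spending_peak = cvd_spending_peak,
    cvd_spending_peak_age = cvd_spending_peak_age,
    cvd_spending_width = cvd_spending_width,
    unrelated_cost_base = unrelated_cost_base,
    unrelated_cost_age_slope = unrelated_cost_age_slope,
    unrelated_cost_terminal = unrelated_cost_terminal,
    population_by_stratum = population_by_stratum,
    age_groups = age_groups, genders = genders,
    closure_age = as.integer(closure_age)
  ), class = "life_surface_params")
}

#' Tabulate synthetic life-table inputs
#'
#' Evaluates the parametric surfaces of [life_surface_params()] on single
#' ages from the youngest starting age to the closure age and packs them into
#' a [life_table_inputs()] container. Quality-of-life values are clipped to
#' \[0, 1\]; costs and rates are nonnegative by construction.
#'
#' @param params A [life_surface_params()] object.
#' @return A `life_table_inputs` object.
#' @export
generate_life_inputs <- function(params) {
  stopifnot(inherits(params, "life_surface_params"))
  p <- params
  ages <- seq(min(age_group_start(p$age_groups)), p$closure_age)
  grid <- expand.grid(age = ages, gender = p$genders,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # mild male excess mortality keeps the two genders distinguishable
  gmult <- ifelse(grid$gender == p$genders[1], 1.2, 0.85)
  rates <- data.frame(
    grid,
    cvd_mortality = p$cvd_a * exp(p$cvd_b * grid$age) * gmult,
    other_mortality = p$gompertz_a * exp(p$gompertz_b * grid$age) * gmult,
    cvd_spending = p$cvd_spending_peak *
      exp(-((grid$age - p$cvd_spending_peak_age) / p$cvd_spending_width)^2),
    stringsAsFactors = FALSE
  )

  horizon <- length(p$qol_ttd_decrements)  # ttd = horizon is background
  ttd <- 0:horizon
  sq <- expand.grid(age = ages, gender = p$genders, ttd = ttd,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dec <- c(p$qol_ttd_decrements, 0)[sq$ttd + 1L]
  qol <- p$qol_at_min_age - p$qol_age_slope * (sq$age - min(ages)) - dec
  qol <- pmin(pmax(qol, 0), 1)
  qol_tab <- data.frame(sq, qol = qol, stringsAsFactors = FALSE)

  ucost <- p$unrelated_cost_base *
    exp(p$unrelated_cost_age_slope * (sq$age - min(ages))) *
    ifelse(sq$ttd == 0, p$unrelated_cost_terminal, 1)
  unrel_tab <- data.frame(sq, cost = ucost, stringsAsFactors = FALSE)

  pop <- expand.grid(age_group = p$age_groups, gender = p$genders,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pop$start_age <- age_group_start(pop$age_group)
  pop$population <- p$population_by_stratum

  life_table_inputs(rates = rates, qol = qol_tab, unrelated = unrel_tab,
                    population = pop, closure_age = p$closure_age)
}
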