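# Shared fixtures and independent oracles, all built in code.

# Hand-built panel: one stratum unless more labels are given.
manual_panel <- function(mortality, spending, years = NULL,
                         age_group = "60-64", gender = "male",
                         population = 1000) {
  years <- years %||% seq(2000, length.out = length(mortality))
  data.frame(age_group = age_group, gender = gender, year = years,
             mortality_rate = mortality, spending = spending,
             population = population, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small fully explicit life-table inputs. Ages start_age .. start_age+n-1,
# one gender ("f") unless two = TRUE. qol and unrelated cost surfaces are
# given as functions of (age, ttd) so structure is easy to vary.
toy_life_inputs <- function(n = 3, start_age = 60,
                            cvd = rep(0.02, n), other = rep(0.01, n),
                            spend = rep(100, n),
                            qol_fn = function(age, ttd) 1,
                            ucost_fn = function(age, ttd) 0,
                            horizon = 2, two = FALSE,
                            population = 1000) {
  genders <- if (two) c("f", "m") else "f"
  ages <- seq(start_age, length.out = n)
  grid <- expand.grid(age = ages, gender = genders, stringsAsFactors = FALSE)
  rates <- data.frame(grid,
                      cvd_mortality = rep(cvd, length(genders)),
                      other_mortality = rep(other, length(genders)),
                      cvd_spending = rep(spend, length(genders)),
                      stringsAsFactors = FALSE)
  sq <- expand.grid(age = ages, gender = genders, ttd = 0:horizon,
                    stringsAsFactors = FALSE)
  qol <- data.frame(sq, qol = mapply(qol_fn, sq$age, sq$ttd))
  unrel <- data.frame(sq, cost = mapply(ucost_fn, sq$age, sq$ttd))
  pop <- data.frame(age_group = paste0(start_age, "+"), gender = genders,
                    start_age = start_age,
                    population = population, stringsAsFactors = FALSE)
  life_table_inputs(rates = rates, qol = qol, unrelated = unrel,
                    population = pop, closure_age = max(ages))
}

# Brute-force oracle: enumerate every possible death year d, weight by its
# exact probability, and accumulate discounted quantities with plain loops.
# Independent of the package's vectorized projection path.
enum_oracle <- function(inputs, start_age, gender,
                        discounts = discount_spec(),
                        cvd_override = NULL, spend_override = NULL) {
  ages <- seq(start_age, inputs$closure_age)
  N <- length(ages)
  H <- inputs$ttd_horizon
  r <- inputs$rates[inputs$rates$gender == gender, ]
  cvd <- cvd_override %||% r$cvd_mortality[match(ages, r$age)]
  other <- r$other_mortality[match(ages, r$age)]
  spend <- spend_override %||% r$cvd_spending[match(ages, r$age)]
  qol_of <- function(age, ttd) {
    k <- min(ttd, H)
    inputs$qol$qol[inputs$qol$age == age & inputs$qol$gender == gender &
                     inputs$qol$ttd == k]
  }
  ucost_of <- function(age, ttd) {
    k <- min(ttd, H)
    inputs$unrelated$cost[inputs$unrelated$age == age &
                            inputs$unrelated$gender == gender &
                            inputs$unrelated$ttd == k]
  }
  q <- 1 - exp(-(cvd + other))
  q[N] <- 1
  de <- (1 + discounts$effect_rate)^-(0:(N - 1))
  dc <- (1 + discounts$cost_rate)^-(0:(N - 1))
  qaly <- ly <- ucost <- ccost <- 0
  for (d in 1:N) {                       # death in year d (1-based)
    pd <- q[d]
    if (d > 1) pd <- pd * prod(1 - q[1:(d - 1)])
    for (y in 1:d) {                     # every year lived, incl. death year
      qaly <- qaly + pd * de[y] * qol_of(ages[y], d - y)
      ly <- ly + pd * de[y]
      ucost <- ucost + pd * dc[y] * ucost_of(ages[y], d - y)
      ccost <- ccost + pd * dc[y] * spend[y]
    }
  }
  list(qaly = qaly, life_years = ly, cvd_cost = ccost,
       unrelated_cost = ucost, total_cost = ccost + ucost)
}

quick_mcmc <- function(seed = 1, n_chains = 2, n_iter = 3000, burn_in = 500,
                       thin = 1) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
              thin = thin, seed = seed)
}

# Small default-shaped simulated panel for reuse across tests.
small_sim <- function(seed = 1, ...) {
  generate_panel(true_panel_params(
    years = c(2000, 2007),
    age_groups = c("60-64", "70-74"), seed = seed, ...))
}
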