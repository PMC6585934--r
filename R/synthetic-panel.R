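# Synthetic spending/mortality panel generator.
#
# The generator draws from exactly the model the estimation stage assumes:
# year-over-year changes in log cause-specific mortality respond to current
# and one-year-lagged changes in log per-capita hospital spending, plus a
# common drift, a year random intercept, a stratum (age x gender) random
# intercept, and observation noise. Spending paths are exogenous (random walk
# with drift); there is no feedback from mortality to spending.

#' Parameters of the generative panel model
#'
#' Bundles the "truth" used by [generate_panel()]: the drift `mu` of log
#' mortality, the instantaneous (`alpha`) and one-year-lagged (`beta`)
#' spending elasticities, the residual standard deviation `sigma_m`, the
#' standard deviations of the year (`sigma_gamma`) and stratum (`sigma_tau`)
#' random intercepts, the stratum grid, baseline levels, and the exogenous
#' log-spending increment process.
#'
#' Defaults describe an elderly cardiovascular panel: 8 five-year age groups
#' (60-64 ... 95+) for both genders over 1994-2010, baseline mortality rising
#' Gompertz-like with age, per-capita spending peaking around age 80, spending
#' growing about 4.4% per year on the log scale (a doubling over 16 years)
#' with stratum-level noise, and mortality drifting down 4% per year.
#'
#' @param mu Drift of log mortality per year.
#' @param alpha Instantaneous spending elasticity of mortality.
#' @param beta One-year-lagged spending elasticity of mortality.
#' @param sigma_m Residual SD of the change in log mortality (>= 0).
#' @param sigma_gamma SD of year random intercepts (>= 0).
#' @param sigma_tau SD of stratum random intercepts (>= 0).
#' @param years Inclusive calendar range, e.g. `c(1994, 2010)`. At least
#'   three years are required (differencing plus the lag consume two).
#' @param age_groups Ordered age-group labels.
#' @param genders Two gender labels.
#' @param m0 Baseline mortality rate per stratum (deaths per person-year, in
#'   (0,1)). Either one value per stratum (ordered age within gender) or a
#'   function of (age_group_index, gender_index). Default: Gompertz in age.
#' @param c0 Baseline per-capita spending per stratum (> 0), same conventions
#'   as `m0`. Default: a bump peaking near age 80.
#' @param spend_trend Deterministic drift of log spending per year (recycled
#'   across strata).
#' @param spend_sd SD of stratum-level log-spending increment noise (>= 0).
#' @param population Persons per stratum (recycled).
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return An object of class `true_panel_params`.
#' @export
true_panel_params <- function(mu = -0.04,
                              alpha = -0.065,
                              beta = -0.124,
                              sigma_m = 0.05,
                              sigma_gamma = 0.02,
                              sigma_tau = 0.01,
                              years = c(1994, 2010),
                              age_groups = c("60-64", "65-69", "70-74",
                                             "75-79", "80-84", "85-89",
                                             "90-94", "95+"),
                              genders = c("male", "female"),
                              m0 = NULL,
                              c0 = NULL,
                              spend_trend = 0.044,
                              spend_sd = 0.10,
                              population = 1e5,
                              seed = 1L) {
  if (length(years) != 2 || years[2] < years[1])
    stop_kthresh("'years' must be c(first, last) with first <= last")
  n_years <- years[2] - years[1] + 1L
  if (n_years < 3)
    stop_kthresh("at least 3 years are required (differencing plus lag consume two)")
  if (any(c(sigma_m, sigma_gamma, sigma_tau, spend_sd) < 0))
    stop_kthresh("sigma_m, sigma_gamma, sigma_tau and spend_sd must be >= 0")
  if (length(genders) != 2)
    stop_kthresh("exactly two gender labels are required")

  n_age <- length(age_groups)
  age_mid <- age_group_start(age_groups) + 2
  if (is.null(m0)) {
    # Gompertz-like baseline, slightly higher for men
    m0 <- as.vector(outer(0.0025 * exp(0.095 * (age_mid - 62)),
                          c(1.25, 0.85)))
  }
  if (is.null(c0)) {
    # per-capita spending peaking near age 80
    c0 <- as.vector(outer(900 * exp(-((age_mid - 80) / 18)^2),
                          c(1.15, 0.9)))
  }
  n_strata <- n_age * length(genders)
  m0 <- rep_len(m0, n_strata)
  c0 <- rep_len(c0, n_strata)
  if (any(m0 <= 0) || any(m0 >= 1))
    stop_kthresh("m0 must lie in (0, 1): it is a rate per person-year")
  if (any(c0 <= 0))
    stop_kthresh("c0 must be > 0")

  structure(list(
    mu = mu, alpha = alpha, beta = beta,
    sigma_m = sigma_m, sigma_gamma = sigma_gamma, sigma_tau = sigma_tau,
    years = as.integer(years), age_groups = age_groups, genders = genders,
    m0 = m0, c0 = c0,
    spend_trend = rep_len(spend_trend, n_strata),
    spend_sd = spend_sd,
    population = rep_len(population, n_strata),
    seed = as.integer(seed)
  ), class = "true_panel_params")
}

# First single year of an age-group label such as "60-64" or "95+".
age_group_start <- function(labels) {
  as.integer(sub("[^0-9].*$", "", labels))
}

#' Generate a synthetic spending/mortality panel
#'
#' Simulates the panel model forward: spending follows an exogenous log
#' random walk with drift (one extra pre-sample year is simulated internally
#' so the lagged spending change is defined for every transition), year and
#' stratum random intercepts are drawn once, and log mortality accumulates
#' the drift, the spending effects, the intercepts and observation noise
#' onto the baseline `m0`.
#'
#' @param params A [true_panel_params()] object.
#' @return An object of class `panel_sim`: a list with `panel` (the dataset:
#'   age_group, gender, year, mortality_rate, spending, population) and
#'   `truth` (realized `gamma` per year, `tau` per stratum, and the
#'   parameters) in a sidecar so that recovery tests can see the truth while
#'   the fitting stage reads only `panel`.
#' @export
generate_panel <- function(params) {
  stopifnot(inherits(params, "true_panel_params"))
  p <- params
  years <- seq(p$years[1], p$years[2])
  n_t <- length(years)
  strata <- expand.grid(age_group = p$age_groups, gender = p$genders,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_a <- nrow(strata)

  set.seed(p$seed)
  gamma <- rnorm(n_t, 0, p$sigma_gamma)     # year intercepts (years 2..T used)
  tau <- rnorm(n_a, 0, p$sigma_tau)         # stratum intercepts

  # log spending: pre-sample year + observed years, random walk with drift
  dlogc <- matrix(rnorm(n_a * n_t, mean = rep(p$spend_trend, n_t),
                        sd = p$spend_sd),
                  nrow = n_a, ncol = n_t)   # increment into years 1..T
  logc <- matrix(0, n_a, n_t + 1L)          # column 1 = pre-sample year
  logc[, 1] <- log(p$c0) - p$spend_trend    # anchor so year 1 is near c0
  for (j in seq_len(n_t)) logc[, j + 1L] <- logc[, j] + dlogc[, j]

  logm <- matrix(0, n_a, n_t)
  logm[, 1] <- log(p$m0)
  eps <- matrix(rnorm(n_a * (n_t - 1L), 0, p$sigma_m), n_a, n_t - 1L)
  for (j in 2:n_t) {
    dlc <- logc[, j + 1L] - logc[, j]       # current-year spending change
    dlc_lag <- logc[, j] - logc[, j - 1L]   # previous-year spending change
    logm[, j] <- logm[, j - 1L] + p$mu + p$alpha * dlc + p$beta * dlc_lag +
      gamma[j] + tau + eps[, j - 1L]
  }
  if (!all(is.finite(logm))) {
    bad <- which(!is.finite(logm), arr.ind = TRUE)[1, ]
    stop_kthresh(sprintf(
      "log mortality became non-finite in stratum %s/%s (year %d): check drift and noise scales",
      strata$age_group[bad[1]], strata$gender[bad[1]], years[bad[2]]))
  }

  panel <- data.frame(
    age_group = rep(strata$age_group, n_t),
    gender = rep(strata$gender, n_t),
    year = rep(years, each = n_a),
    mortality_rate = as.vector(exp(logm)),
    spending = as.vector(exp(logc[, -1L, drop = FALSE])),
    population = rep(p$population, n_t),
    stringsAsFactors = FALSE
  )
  panel <- panel[order(panel$gender, panel$age_group, panel$year), ]
  rownames(panel) <- NULL
  validate_panel(panel)

  truth <- list(
    gamma = data.frame(year = years, gamma = gamma),
    tau = data.frame(age_group = strata$age_group, gender = strata$gender,
                     tau = tau, stringsAsFactors = FALSE),
    params = p
  )
  structure(list(panel = panel, truth = truth), class = "panel_sim")
}

#' Validate a spending/mortality panel
#'
#' Checks the panel dataset contract: required columns, strictly positive
#' mortality and spending (logs must exist), exactly one row per stratum and
#' year, and consecutive years within each stratum.
#'
#' @param panel A data frame with columns age_group, gender, year,
#'   mortality_rate, spending, population.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  need <- c("age_group", "gender", "year", "mortality_rate", "spending",
            "population")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop_kthresh(paste("panel is missing columns:", paste(miss, collapse = ", ")))
  bad <- which(!(panel$mortality_rate > 0) | !(panel$spending > 0) |
                 !is.finite(panel$mortality_rate) | !is.finite(panel$spending))
  if (length(bad)) {
    b <- bad[1]
    stop_kthresh(sprintf(
      "nonpositive or non-finite mortality/spending in stratum %s/%s, year %d",
      panel$age_group[b], panel$gender[b], panel$year[b]))
  }
  key <- interaction(panel$age_group, panel$gender, drop = TRUE)
  for (s in levels(key)) {
    yrs <- sort(panel$year[key == s])
    if (anyDuplicated(yrs))
      stop_kthresh(sprintf("duplicate year rows in stratum %s", s))
    if (length(yrs) > 1 && any(diff(yrs) != 1L))
      stop_kthresh(sprintf("gap in years within stratum %s", s))
  }
  invisible(panel)
}

#' Write / read a panel (and its truth sidecar) as delimited text
#'
#' Plain headered CSV with "." decimal. The sidecar truth tables are written
#' next to the panel with suffixes `_truth_gamma.csv` / `_truth_tau.csv` so
#' the fitting stage can be pointed at the panel file alone.
#'
#' @param sim A `panel_sim` object (or a bare panel data frame for
#'   `write_panel`).
#' @param path Path of the panel CSV.
#' @return `write_panel` the path invisibly; `read_panel` a validated panel
#'   data frame.
#' @export
write_panel <- function(sim, path) {
  panel <- if (inherits(sim, "panel_sim")) sim$panel else sim
  validate_panel(panel)
  write.csv(panel, path, row.names = FALSE, quote = FALSE)
  if (inherits(sim, "panel_sim")) {
    base <- sub("\\.csv$", "", path)
    write.csv(sim$truth$gamma, paste0(base, "_truth_gamma.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(sim$truth$tau, paste0(base, "_truth_tau.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}
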