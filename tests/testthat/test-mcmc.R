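frame_small <- build_model_frame(small_sim(seed = 12)$panel)

test_that("same frame, priors, config, seed give identical retained draws", {
  cfg <- quick_mcmc(seed = 3, n_iter = 800, burn_in = 200)
  a <- fit_mcmc(frame_small, prior_spec(), cfg, diagnostics = FALSE)
  b <- fit_mcmc(frame_small, prior_spec(), cfg, diagnostics = FALSE)
  expect_identical(a$draws, b$draws)
  cfg2 <- quick_mcmc(seed = 4, n_iter = 800, burn_in = 200)
  c <- fit_mcmc(frame_small, prior_spec(), cfg2, diagnostics = FALSE)
  expect_false(identical(a$draws$alpha, c$draws$alpha))
})

test_that("retained-draw bookkeeping matches the thinning formula", {
  cfg <- mcmc_config(n_chains = 3, n_iter = 700, burn_in = 300, thin = 4,
                     seed = 1)
  fit <- fit_mcmc(frame_small, prior_spec(), cfg, diagnostics = FALSE)
  expect_equal(nrow(fit$draws), 3 * (700 - 300) / 4)
  expect_equal(retained_draws(cfg), 300)
  expect_equal(unname(table(fit$draws$chain)), rep(100L, 3),
               ignore_attr = TRUE)
})

test_that("zero spending variation: elasticity posterior equals its prior", {
  set.seed(41)
  panel <- rbind(
    manual_panel(exp(cumsum(rnorm(6, -0.02, 0.01))), rep(5, 6)),
    manual_panel(exp(cumsum(rnorm(6, -0.02, 0.01))), rep(8, 6),
                 age_group = "65-69"))
  frame <- build_model_frame(panel)
  pri <- prior_spec(alpha_prior = c(0.4, 0.25), beta_prior = c(-0.3, 0.2))
  expect_warning(
    fit <- fit_mcmc(frame, pri, quick_mcmc(seed = 6, n_iter = 4000,
                                           burn_in = 500),
                    diagnostics = FALSE),
    "no information on elasticity")
  expect_true(any(grepl("no information", fit$flags)))
  n_eff <- 2 * 3500
  expect_lt(abs(mean(fit$draws$alpha) - 0.4), 5 * 0.25 / sqrt(n_eff))
  expect_equal(sd(fit$draws$alpha), 0.25, tolerance = 0.05)
  expect_lt(abs(mean(fit$draws$beta) + 0.3), 5 * 0.2 / sqrt(n_eff))
})

test_that("sigma draws respect the uniform prior support", {
  pri <- prior_spec(sigma_m_prior = c(0.02, 0.08),
                    sigma_gamma_prior = c(0, 0.5),
                    sigma_tau_prior = c(0.001, 0.3))
  fit <- fit_mcmc(frame_small, pri, quick_mcmc(seed = 2, n_iter = 1000,
                                               burn_in = 200),
                  diagnostics = FALSE)
  expect_true(all(fit$draws$sigma_m >= 0.02 & fit$draws$sigma_m <= 0.08))
  expect_true(all(fit$draws$sigma_gamma <= 0.5))
  expect_true(all(fit$draws$sigma_tau >= 0.001 & fit$draws$sigma_tau <= 0.3))
})

test_that("binding sigma truncation is flagged", {
  # true residual sd 3 against a uniform(0,1) prior, random effects pinned
  # at zero so nothing else can absorb the spread: posterior piles at 1
  set.seed(8)
  panel <- rbind(
    manual_panel(exp(cumsum(rnorm(8, 0, 3))), exp(cumsum(rnorm(8, 0, 0.1)))),
    manual_panel(exp(cumsum(rnorm(8, 0, 3))), exp(cumsum(rnorm(8, 0, 0.1))),
                 age_group = "65-69"))
  frame <- build_model_frame(panel)
  pri <- prior_spec(sigma_gamma_prior = c(0, 0), sigma_tau_prior = c(0, 0))
  expect_warning(
    fit <- fit_mcmc(frame, pri,
                    quick_mcmc(seed = 3, n_iter = 1500, burn_in = 300),
                    diagnostics = FALSE),
    "truncation")
  expect_true(any(grepl("sigma_m", fit$flags)))
})

test_that("degenerate-sigma posterior matches the conjugate normal oracle", {
  sim <- generate_panel(true_panel_params(
    years = c(2000, 2005), age_groups = c("60-64", "65-69"),
    genders = c("male", "female"),
    sigma_gamma = 0, sigma_tau = 0, sigma_m = 0.04, seed = 31))
  frame <- build_model_frame(sim$panel)
  s <- 0.04
  pri <- prior_spec(sigma_m_prior = c(s, s), sigma_gamma_prior = c(0, 0),
                    sigma_tau_prior = c(0, 0))
  X <- cbind(1, frame$dlog_c, frame$dlog_c_lag)
  y <- frame$dlog_m
  # independent closed form: V = (P0 + X'X/s^2)^-1, m = V X'y / s^2
  V <- solve(diag(1 / 10, 3) + crossprod(X) / s^2)
  m <- as.vector(V %*% (crossprod(X, y) / s^2))
  fit <- fit_mcmc(frame, pri,
                  quick_mcmc(seed = 7, n_iter = 5000, burn_in = 500))
  draws <- fit$draws[c("mu", "alpha", "beta")]
  ess <- fit$diagnostics$summary$ess[
    match(c("mu", "alpha", "beta"), fit$diagnostics$summary$parameter)]
  for (j in 1:3) {
    mcse <- sd(draws[[j]]) / sqrt(ess[j])
    expect_lt(abs(mean(draws[[j]]) - m[j]), 3 * mcse)
    expect_equal(sd(draws[[j]]), sqrt(V[j, j]), tolerance = 0.1)
  }
  # sigmas pinned: gamma and tau stay at zero, sigma_m at its value
  expect_true(all(fit$draws$sigma_m == s))
  expect_true(all(fit$draws[[grep("^gamma_", names(fit$draws), value = TRUE)[1]]] == 0))
})

test_that("no-lag fit drops beta and reports alpha as the elasticity", {
  fit <- fit_mcmc(frame_small, prior_spec(),
                  quick_mcmc(seed = 5, n_iter = 600, burn_in = 100),
                  include_lag = FALSE, diagnostics = FALSE)
  expect_false("beta" %in% names(fit$draws))
  expect_false("alpha_plus_beta" %in% names(fit$draws))
  expect_identical(elasticity_draws(fit), fit$draws$alpha)
})

test_that("draws round-trip through delimited text with metadata", {
  fit <- fit_mcmc(frame_small, prior_spec(),
                  quick_mcmc(seed = 5, n_iter = 400, burn_in = 100),
                  diagnostics = FALSE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "draws.csv")
  write_draws(fit, path)
  expect_true(file.exists(file.path(dir, "draws_meta.csv")))
  back <- read_draws(path)
  expect_equal(back$alpha, fit$draws$alpha, tolerance = 1e-12)
  expect_equal(attr(back, "n_chains"), 2)
})
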