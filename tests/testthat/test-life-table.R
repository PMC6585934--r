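test_that("adjust_mortality conventions", {
  expect_equal(adjust_mortality(0.02, 1.1, 0), 0.02)
  expect_equal(adjust_mortality(0.02, 1, -0.5), 0.02)
  expect_equal(adjust_mortality(0.02, 1.1, -0.19), 0.02 * 1.1^-0.19,
               tolerance = 1e-12)
  expect_equal(adjust_mortality(0.02, 1.1, -0.19), 0.0196411,
               tolerance = 1e-6)
  # literal linear reading
  expect_equal(adjust_mortality(0.02, 1.1, -0.19, mode = "linear"),
               0.02 * (1 + 0.9 * -0.19 * 0.1), tolerance = 1e-12)
  expect_error(adjust_mortality(0.02, 13, -1, mode = "linear"), "negative")
  expect_error(adjust_mortality(-0.01, 1.1, 0), ">= 0")
  expect_error(adjust_mortality(0.02, 0, 0), "> 0")
})

test_that("flat qol and zero discounting: QALYs = life years = sum of survival", {
  li <- toy_life_inputs(n = 4, cvd = c(0.1, 0.2, 0.3, 1),
                        other = rep(0.05, 4))
  pr <- project_cohort(li, 60, "f", discount_spec(0, 0))
  q <- 1 - exp(-(c(0.1, 0.2, 0.3, 1) + 0.05))
  q[4] <- 1
  S <- cumprod(c(1, 1 - q[1:3]))
  expect_equal(pr$totals$qaly, sum(S), tolerance = 1e-12)
  expect_equal(pr$totals$life_years, sum(S), tolerance = 1e-12)
  expect_equal(pr$table$survival, S, tolerance = 1e-12)
})

test_that("certain death in year 0: one-cycle world", {
  li <- toy_life_inputs(n = 3, cvd = c(1e9, 0.1, 0.1),
                        other = rep(0, 3),
                        qol_fn = function(age, ttd) if (ttd == 0) 0.8 else 1)
  pr <- project_cohort(li, 60, "f", discount_spec(0, 0))
  expect_equal(pr$totals$qaly, 0.8, tolerance = 1e-9)
  expect_equal(pr$totals$life_years, 1, tolerance = 1e-9)
  expect_equal(pr$table$death_prob[1], 1, tolerance = 1e-9)
})

test_that("fixed 3-year lifespan: discounted cost is the geometric sum", {
  li <- toy_life_inputs(n = 3, cvd = rep(0, 3), other = rep(0, 3),
                        spend = rep(100, 3))
  pr <- project_cohort(li, 60, "f", discount_spec(0.04, 0.015))
  expect_equal(pr$totals$cvd_cost, 100 * (1 + 1 / 1.04 + 1 / 1.04^2),
               tolerance = 1e-10)
  expect_equal(pr$totals$cvd_cost, 288.6095, tolerance = 1e-6)
  # survives to closure with certainty, then dies
  expect_equal(pr$table$death_prob, c(0, 0, 1))
})

test_that("conservation: death probabilities sum to one at closure", {
  li <- generate_life_inputs(life_surface_params())
  for (g in c("male", "female")) {
    pr <- project_cohort(li, 75, g)
    expect_equal(sum(pr$table$death_prob), 1, tolerance = 1e-12)
    expect_true(all(diff(pr$table$survival) <= 1e-14))
    expect_lte(pr$totals$qaly, pr$totals$life_years)
  }
})

test_that("projection equals the brute-force death-year enumeration", {
  li <- toy_life_inputs(
    n = 5, cvd = c(0.05, 0.1, 0.2, 0.4, 0.6), other = 0.02 * 1:5,
    spend = c(100, 150, 200, 150, 100),
    qol_fn = function(age, ttd) max(0, 0.9 - 0.02 * (age - 60) -
                                      c(0.3, 0.1, 0)[min(ttd, 2) + 1]),
    ucost_fn = function(age, ttd) 500 * (1 + (ttd == 0) * 4) + 10 * (age - 60),
    horizon = 2)
  for (disc in list(discount_spec(0, 0), discount_spec(0.04, 0.015))) {
    pr <- project_cohort(li, 60, "f", disc)
    or <- enum_oracle(li, 60, "f", disc)
    expect_equal(pr$totals$qaly, or$qaly, tolerance = 1e-12)
    expect_equal(pr$totals$life_years, or$life_years, tolerance = 1e-12)
    expect_equal(pr$totals$cvd_cost, or$cvd_cost, tolerance = 1e-12)
    expect_equal(pr$totals$unrelated_cost, or$unrelated_cost,
                 tolerance = 1e-12)
  }
})

test_that("missing surface cells are named", {
  li <- toy_life_inputs(n = 3)
  li$qol <- li$qol[!(li$qol$age == 61 & li$qol$ttd == 1), ]
  expect_error(project_cohort(li, 60, "f"), "age 61, ttd 1")
})

test_that("zero elasticity: no QALY change, cost delta is the spending PV", {
  li <- toy_life_inputs(n = 4, cvd = c(0.05, 0.1, 0.2, 0.4),
                        other = rep(0.01, 4), spend = c(100, 120, 90, 60),
                        ucost_fn = function(age, ttd) 300)
  d <- scenario_delta(li, elasticity = 0, spend_increase = 0.10,
                      discounts = discount_spec(0.04, 0.015))
  expect_identical(d$delta_qaly, 0)
  expect_identical(d$delta_ly, 0)
  # independent PV of the 10% increment over baseline survivorship
  pr <- project_cohort(li, 60, "f", discount_spec(0.04, 0.015))
  pv <- sum(pr$table$survival * c(100, 120, 90, 60) * 0.1 / 1.04^(0:3))
  expect_equal(d$delta_cost, pv, tolerance = 1e-10)
})

test_that("protective elasticity lengthens life", {
  li <- generate_life_inputs(life_surface_params())
  d <- scenario_delta(li, elasticity = -0.19)
  expect_gt(d$delta_qaly, 0)
  expect_gt(d$delta_ly, 0)
  expect_equal(d$elasticity_used, -0.19)
})

test_that("QALY gain is strictly increasing in |elasticity|", {
  li <- toy_life_inputs(n = 5, cvd = c(0.05, 0.1, 0.2, 0.3, 0.5),
                        other = rep(0.02, 5), two = TRUE)
  grid <- seq(0, 1.5, by = 0.25)
  dq <- vapply(-grid, function(e) scenario_delta(li, e)$delta_qaly, 0)
  expect_true(all(diff(dq) > 0))
})

test_that("compare_states: identity, consistency with scenario_delta, mismatch", {
  li <- toy_life_inputs(n = 4, cvd = c(0.05, 0.1, 0.2, 0.4),
                        other = rep(0.02, 4), spend = c(80, 100, 90, 70),
                        ucost_fn = function(age, ttd) 200 + 50 * (ttd == 0))
  z <- compare_states(li, li)
  expect_equal(z$delta_cost, 0)
  expect_equal(z$delta_qaly, 0)

  # alternative built exactly as scenario_delta builds it
  alt <- li
  alt$rates$cvd_spending <- li$rates$cvd_spending * 1.1
  alt$rates$cvd_mortality <- adjust_mortality(li$rates$cvd_mortality, 1.1,
                                              -0.25)
  cs <- compare_states(li, alt)
  sd_ <- scenario_delta(li, -0.25, spend_increase = 0.10)
  expect_equal(cs$delta_cost, sd_$delta_cost, tolerance = 1e-12)
  expect_equal(cs$delta_qaly, sd_$delta_qaly, tolerance = 1e-12)
  expect_equal(cs$delta_ly, sd_$delta_ly, tolerance = 1e-12)

  # two-age hand-built example vs the enumeration oracle
  li2 <- toy_life_inputs(n = 2, cvd = c(0.3, 1), other = c(0.1, 0.2),
                         spend = c(50, 60),
                         qol_fn = function(age, ttd) 0.8 - 0.2 * (ttd == 0),
                         ucost_fn = function(age, ttd) 100 * (1 + (ttd == 0)))
  alt2 <- li2
  alt2$rates$cvd_mortality <- c(0.2, 0.8)
  alt2$rates$cvd_spending <- c(70, 80)
  cs2 <- compare_states(li2, alt2, discount_spec(0.04, 0.015))
  ob <- enum_oracle(li2, 60, "f", discount_spec(0.04, 0.015))
  oa <- enum_oracle(alt2, 60, "f", discount_spec(0.04, 0.015))
  expect_equal(cs2$delta_qaly, oa$qaly - ob$qaly, tolerance = 1e-12)
  expect_equal(cs2$delta_cost, oa$total_cost - ob$total_cost,
               tolerance = 1e-12)

  bad <- toy_life_inputs(n = 5, cvd = rep(0.1, 5), other = rep(0.02, 5))
  expect_error(compare_states(li, bad), "grid mismatch")
})

test_that("discounting limit: constant hazard matches the closed form", {
  lam <- 0.2
  n <- 40
  li <- toy_life_inputs(n = n, cvd = rep(lam, n), other = rep(0, n))
  pr <- project_cohort(li, 60, "f", discount_spec(0, 0))
  q <- 1 - exp(-lam)
  # discrete closed form: sum_{y=0}^{n-1} (1-q)^y
  expect_equal(pr$totals$life_years, sum((1 - q)^(0:(n - 1))),
               tolerance = 1e-10)
  expect_equal(pr$totals$life_years, (1 - (1 - q)^n) / q, tolerance = 1e-10)
})
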