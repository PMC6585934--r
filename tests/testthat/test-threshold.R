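li_thr <- toy_life_inputs(
  n = 5, cvd = c(0.05, 0.1, 0.2, 0.35, 0.6), other = 0.02 * 1:5,
  spend = c(100, 150, 180, 150, 100),
  qol_fn = function(age, ttd) 0.85 - 0.15 * (ttd == 0),
  ucost_fn = function(age, ttd) 400 * (1 + 3 * (ttd == 0)), two = TRUE)

test_that("identical draws collapse the summary onto a single ratio", {
  ts <- summarize_threshold(rep(-0.2, 25), li_thr)
  d <- scenario_delta(li_thr, -0.2)
  expect_equal(ts$cost_per_qaly, d$delta_cost / d$delta_qaly,
               tolerance = 1e-12)
  expect_equal(ts$ci95_qaly[1], ts$ci95_qaly[2], tolerance = 1e-12)
  expect_equal(ts$ci95_qaly[1], ts$cost_per_qaly, tolerance = 1e-12)
  expect_equal(ts$share_nonpositive_dqaly, 0)
  expect_equal(ts$n_draws, 25)
})

test_that("doubling all cost surfaces doubles the threshold exactly", {
  e <- c(-0.3, -0.2, -0.15, -0.25)
  li2 <- li_thr
  li2$rates$cvd_spending <- li_thr$rates$cvd_spending * 2
  li2$unrelated$cost <- li_thr$unrelated$cost * 2
  a <- summarize_threshold(e, li_thr)
  b <- summarize_threshold(e, li2)
  expect_equal(b$cost_per_qaly, 2 * a$cost_per_qaly, tolerance = 1e-12)
  expect_equal(b$ci95_qaly, 2 * a$ci95_qaly, tolerance = 1e-12)
  expect_equal(b$cost_per_ly, 2 * a$cost_per_ly, tolerance = 1e-12)
})

test_that("two-draw toy set matches hand-computed conventions", {
  e <- c(-0.3, -0.1)
  f <- function(el) scenario_delta(li_thr, el)
  d1 <- f(-0.3); d2 <- f(-0.1)
  ts <- summarize_threshold(e, li_thr)
  expect_equal(ts$cost_per_qaly,
               mean(c(d1$delta_cost, d2$delta_cost)) /
                 mean(c(d1$delta_qaly, d2$delta_qaly)), tolerance = 1e-12)
  # interval: ratio evaluated at the 0.025/0.975 elasticity quantiles
  qs <- quantile(e, c(0.025, 0.975), names = FALSE)
  r <- vapply(qs, function(el) {
    d <- f(el); d$delta_cost / d$delta_qaly
  }, 0)
  expect_equal(ts$ci95_qaly, sort(r), tolerance = 1e-12)
})

test_that("life years are cheaper than QALYs when qol < 1 on the path", {
  ts <- summarize_threshold(c(-0.25, -0.2, -0.3), li_thr)
  expect_lt(ts$cost_per_ly, ts$cost_per_qaly)
})

test_that("non-positive mean QALY gain is flagged, not reported", {
  ts <- expect_silent(summarize_threshold(c(0.2, 0.3), li_thr))
  expect_true(is.na(ts$cost_per_qaly))
  expect_match(ts$flags, "undefined")
  expect_equal(ts$share_nonpositive_dqaly, 1)
})

test_that("probability curve: step function for identical draws", {
  d <- scenario_delta(li_thr, -0.2)
  v <- d$delta_cost / d$delta_qaly   # the per-draw ratio, same code path
  grid <- c(v - 2, v - 1e-6, v, v + 1, v + 100)
  curve <- probability_below(rep(-0.2, 10), li_thr, grid = grid)
  expect_equal(curve$probability, c(0, 0, 1, 1, 1))
})

test_that("probability curve equals an explicit ECDF oracle", {
  e <- seq(-0.5, -0.05, by = 0.05)
  icers <- vapply(e, function(el) {
    d <- scenario_delta(li_thr, el)
    d$delta_cost / d$delta_qaly
  }, 0)
  grid <- seq(0, 20000, by = 250)
  curve <- probability_below(e, li_thr, grid = grid)
  oracle <- vapply(grid, function(x) mean(icers <= x), 0)
  expect_equal(curve$probability, oracle, tolerance = 1e-12)
  expect_true(all(diff(curve$probability) >= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("draws without QALY gains keep the curve below one", {
  e <- c(rep(-0.2, 6), rep(0.1, 4))   # 40% of draws harm or do nothing
  curve <- probability_below(e, li_thr, grid = c(1e4, 1e6, 1e9))
  expect_true(all(curve$probability <= 0.6 + 1e-12))
  expect_equal(max(curve$probability), 0.6)
  expect_equal(attr(curve, "share_nonpositive_dqaly"), 0.4)
})

test_that("grid must be non-empty and ascending", {
  expect_error(probability_below(c(-0.2), li_thr, grid = numeric(0)),
               "non-empty")
  expect_error(probability_below(c(-0.2), li_thr, grid = c(3, 2, 1)),
               "ascending")
})

test_that("curves and deltas serialize with metadata headers", {
  dir <- withr::local_tempdir()
  curve <- probability_below(c(-0.2, -0.3), li_thr, grid = c(0, 5000, 10000))
  write_curve(curve, file.path(dir, "curve.csv"), meta = list(seed = 1))
  lines <- readLines(file.path(dir, "curve.csv"))
  expect_match(lines[1], "^# seed: 1")
  back <- read.csv(file.path(dir, "curve.csv"), comment.char = "#")
  expect_equal(back$probability, curve$probability)

  d <- scenario_delta(li_thr, -0.2)
  write_delta(d, file.path(dir, "delta.csv"),
              meta = list(mode = "power"))
  back2 <- read.csv(file.path(dir, "delta.csv"), comment.char = "#")
  expect_equal(back2$delta_qaly, d$delta_qaly, tolerance = 1e-9)
})
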