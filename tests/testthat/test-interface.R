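minimal_config <- function(out_dir, ...) {
  modifyList(list(
    panel = list(synthetic = list(
      years = c(2000, 2008),
      age_groups = c("60-64", "70-74"))),
    life_inputs = list(synthetic = list(
      age_groups = c("60-64", "70-74"), closure_age = 95)),
    mcmc = list(n_chains = 2, n_iter = 1200, burn_in = 200, thin = 2),
    curve_grid = list(from = 0, to = 1e5, by = 10000),
    seed = 7,
    verbosity = 0,
    output_dir = out_dir
  ), list(...))
}

test_that("minimal config gets protocol defaults filled in", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.json")
  write_config(list(panel = list(synthetic = list()),
                    life_inputs = list(synthetic = list()),
                    seed = 1, output_dir = dir), path)
  cfg <- load_config(path)
  expect_equal(cfg$mcmc$n_iter, 75000)
  expect_equal(cfg$mcmc$burn_in, 25000)
  expect_equal(cfg$mcmc$thin, 4)
  expect_equal(cfg$mcmc$n_chains, 3)
  expect_equal(cfg$discounts$cost_rate, 0.04)
  expect_equal(cfg$discounts$effect_rate, 0.015)
  expect_equal(cfg$spend_increase, 0.10)
  expect_equal(cfg$scenarios, "base")
})

test_that("validation reports all violations at once", {
  err <- tryCatch(
    validate_config(list(
      panel = list(path = "x.csv", synthetic = list()),  # both
      life_inputs = list(),                              # neither
      bogus_key = 1,                                     # unknown
      scenarios = "nope",                                # unknown label
      mcmc = list(n_iter = 100, burn_in = 200, thin = 4, n_chains = 2),
      output_dir = "o"                                   # no seed
    )), error = identity)
  msg <- conditionMessage(err)
  expect_match(msg, "exactly one of")
  expect_match(msg, "unknown keys: bogus_key")
  expect_match(msg, "unknown scenario")
  expect_match(msg, "burn_in must be")
  expect_match(msg, "seed")
})

test_that("configs round-trip through JSON", {
  dir <- withr::local_tempdir()
  cfg <- validate_config(minimal_config(dir))
  path <- file.path(dir, "cfg.json")
  write_config(cfg, path)
  back <- load_config(path)
  expect_equal(back$mcmc$n_iter, cfg$mcmc$n_iter)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$panel$synthetic$years, cfg$panel$synthetic$years)
})

test_that("end-to-end pipeline writes parseable artifacts", {
  dir <- withr::local_tempdir()
  cfg <- validate_config(minimal_config(file.path(dir, "out")))
  res <- run_pipeline(cfg, stages = "all")
  out <- cfg$output_dir
  for (f in c("panel.csv", "draws_base.csv", "diagnostics_base.csv",
              "delta_base.csv", "report.csv", "report.json",
              "curve_base.csv", "manifest.json")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  expect_true(dir.exists(file.path(out, "life_inputs")))
  rep <- read.csv(file.path(out, "report.csv"))
  expect_equal(rep$scenario, "base")
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 7)
  expect_true(length(man$digests) >= 5)
  curve <- read.csv(file.path(out, "curve_base.csv"), comment.char = "#")
  expect_true(all(diff(curve$probability) >= 0))
})

test_that("identical config and seed regenerate identical artifacts", {
  dir <- withr::local_tempdir()
  cfg1 <- validate_config(minimal_config(file.path(dir, "a")))
  cfg2 <- validate_config(minimal_config(file.path(dir, "b")))
  run_pipeline(cfg1, stages = "all")
  run_pipeline(cfg2, stages = "all")
  for (f in c("report.csv", "draws_base.csv", "panel.csv",
              "curve_base.csv")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)), label = f)
  }
})

test_that("stage selection stops early", {
  dir <- withr::local_tempdir()
  cfg <- validate_config(minimal_config(file.path(dir, "out")))
  run_pipeline(cfg, stages = "simulate")
  expect_true(file.exists(file.path(cfg$output_dir, "panel.csv")))
  expect_false(file.exists(file.path(cfg$output_dir, "report.csv")))
})

test_that("a window with no data aborts with the stage name", {
  dir <- withr::local_tempdir()
  cfg <- validate_config(minimal_config(
    file.path(dir, "out"),
    panel = list(synthetic = list(years = c(1994, 1999),
                                  age_groups = c("60-64", "70-74"))),
    scenarios = "years_2001_2010"))
  err <- tryCatch(run_pipeline(cfg), error = identity)
  expect_match(conditionMessage(err), "stage 'fit'")
  expect_match(conditionMessage(err), "year window \\[2001, 2010\\]")
})
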