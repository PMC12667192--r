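# Configuration, presets, recipe runs and the CLI surface.

test_that("empty config yields all defaults; unknown keys are rejected", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$belts$left, 1.0)
  expect_equal(cfg$cerebellum$alpha, 0.002)
  expect_equal(cfg$cerebellum$beta, 0.02)
  expect_true(nzchar(attr(cfg, "hash")))
  writeLines('{"beltz": {"left": 1}}', f)
  expect_error(load_config(f), "unknown configuration key.*beltz")
  writeLines('{"objective": {"weights": {"w_ub": -1}}}', f)
  expect_error(load_config(f), "negative weight")
})

test_that("presets fully determine a run and match hand-written configs", {
  cfg <- recipe_preset("split-belt-with-cerebellum")
  expect_true(cfg$cerebellum$enabled)
  expect_equal(cfg$n_seeds, 10)
  expect_equal(cfg$belts, list(left = 1.0, right = 0.5))
  expect_equal(cfg$simulation$duration, 80)
  grid <- recipe_preset("rate-grid")
  expect_equal(grid$grid$alpha, c(0.01, 0.05))
  expect_equal(grid$grid$beta, c(0.01, 0.04))
  expect_equal(grid$n_seeds, 3)
  ramp <- recipe_preset("belt-ramp")
  expect_equal(ramp$ramp_speeds, seq(0.9, 0.5, by = -0.1))
})

test_that("reflex-only and cerebellum presets differ only in the switch", {
  a <- recipe_preset("split-belt-with-cerebellum")
  b <- recipe_preset("split-belt-reflex-only")
  a$preset <- b$preset <- NULL
  a$cerebellum$enabled <- b$cerebellum$enabled <- NULL
  expect_identical(a, b)
  # free-parameter counts: 64 spinal-only, 66 with the cerebellar rates
  ctrl <- spinal_controller()
  expect_equal(ctrl$n_free, 64L)
  expect_equal(ctrl$n_free + 2L, 66L)  # + alpha, beta
})

test_that("surrogate recipe runs, is deterministic, and carries the hash", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t0 <- Sys.time()
  r1 <- run_recipe("surrogate", seed = 3, out_dir = d1)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 5)
  r2 <- run_recipe("surrogate", seed = 3, out_dir = d2)
  expect_identical(r1$strides, r2$strides)
  expect_true(file.exists(file.path(d1, "strides.csv")))
  expect_true(file.exists(file.path(d1, "cerebellum_log.csv")))
  expect_true(file.exists(file.path(d1, "config.json")))
  st <- utils::read.csv(file.path(d1, "strides.csv"))
  expect_true("config_hash" %in% names(st))
  expect_equal(unique(st$config_hash), r1$config_hash)
})

test_that("CLI surrogate and rate-grid commands produce their outputs", {
  d <- withr::local_tempdir()
  run_cli(c("surrogate", "--alpha", "0.01", "--beta", "0.04",
            "--strides", "60", "--out", d, "--seed", "2"))
  expect_true(file.exists(file.path(d, "strides.csv")))
  run_cli(c("analyze", "--out", d))
  fit <- jsonlite::fromJSON(file.path(d, "sla_fit.json"))
  expect_true(is.finite(fit$a))
  d2 <- withr::local_tempdir()
  run_cli(c("rate-grid", "--strides", "150", "--out", d2))
  rg <- utils::read.csv(file.path(d2, "rate_grid.csv"))
  expect_equal(nrow(rg), 4L)
  expect_error(run_cli(c("surrogate", "--bogus", "1")), "unknown option")
  expect_error(run_cli("frobnicate"), "unknown command")
})

test_that("trajectory writer emits CSV, JSON-lines events and summary", {
  tr <- make_traj(t_end = 50, t_des = 80)
  tr$events <- data.frame(time = c(1, 1.6), leg = c("fast", "slow"),
                          type = c("HS", "HS"))
  d <- withr::local_tempdir()
  write_trajectory(tr, d, config_hash = "abc123")
  ev <- readLines(file.path(d, "events.jsonl"))
  expect_length(ev, 2L)
  expect_equal(jsonlite::fromJSON(ev[1])$leg, "fast")
  s <- jsonlite::fromJSON(file.path(d, "summary.json"))
  expect_equal(s$t_end, 50)
  expect_equal(s$config_hash, "abc123")
})
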