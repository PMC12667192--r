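# CMA-ES harness: benchmark convergence, termination, determinism, and
# the staged ramp bookkeeping.

test_that("CMA-ES solves the 10-D sphere to 1e-6 within 200 generations", {
  sphere <- function(x) sum(x^2)
  cfg <- optimization_config(lambda = 16, sigma = 1, max_gen = 200,
                             stagnation_window = 1000, seed = 3)
  res <- run_cmaes(sphere, rep(3, 10), cfg)
  expect_lt(res$value, 1e-6)
})

test_that("flat objective triggers the stagnation stop at the window", {
  cfg <- optimization_config(lambda = 8, sigma = 1, max_gen = 100,
                             stagnation_window = 20, stagnation_tol = 1e-4,
                             seed = 1)
  res <- run_cmaes(function(x) 1, rep(0, 4), cfg)
  expect_equal(res$stop_reason, "stagnation")
  expect_equal(nrow(res$history), 20L)
})

test_that("fixed seed reproduces the history; non-finite values are handled", {
  fn <- function(x) if (abs(x[1]) > 2) NaN else sum(x^2)
  cfg <- optimization_config(lambda = 8, sigma = 1.5, max_gen = 30,
                             stagnation_window = 1000, seed = 11)
  a <- run_cmaes(fn, c(1.5, 0.5), cfg)
  b <- run_cmaes(fn, c(1.5, 0.5), cfg)
  expect_identical(a$history, b$history)
  expect_gt(a$n_nonfinite, 0)
  expect_true(all(is.finite(a$history$best)))
  # distinct seeds give distinct histories
  cfg2 <- cfg; cfg2$seed <- 12L
  d <- run_cmaes(fn, c(1.5, 0.5), cfg2)
  expect_false(identical(a$history$best, d$history$best))
})

test_that("best-so-far history is monotone non-increasing", {
  cfg <- optimization_config(lambda = 8, max_gen = 50,
                             stagnation_window = 1000, seed = 5)
  res <- run_cmaes(function(x) sum((x - 1)^2) + 0.1 * sum(abs(x)),
                   rep(0, 5), cfg)
  expect_true(all(diff(res$history$best_so_far) <= 0))
})

test_that("belt ramp warm-starts each stage from the previous best", {
  # toy stage objective: optimum moves with the right-belt speed
  factory <- function(sp) function(x) sum((x - sp)^2)
  cfg <- optimization_config(lambda = 8, sigma = 0.5, max_gen = 40,
                             stagnation_window = 1000, seed = 2)
  ramp <- belt_ramp_protocol(rep(1, 3), factory,
                             speeds = seq(0.9, 0.5, by = -0.1),
                             config = cfg)
  expect_true(ramp$completed)
  expect_equal(length(ramp$stages), 5L)
  for (k in 2:5) {
    expect_identical(ramp$stages[[k]]$warm_start, ramp$stages[[k - 1]]$par)
  }
  expect_equal(unname(ramp$par), rep(0.5, 3), tolerance = 1e-2)
  # a failing stage halts the protocol with a report
  ramp2 <- belt_ramp_protocol(rep(1, 3), factory,
                              speeds = seq(0.9, 0.5, by = -0.1),
                              config = cfg,
                              check = function(par, sp) sp > 0.75)
  expect_false(ramp2$completed)
  expect_equal(ramp2$failed_speed, 0.7)
  expect_equal(length(ramp2$stages), 3L)
})

test_that("manual readjustment replaces exactly the named parameters", {
  p <- c(sol_f_gain = 1, gas_f_gain = 2, il_l_gain = 3)
  expect_identical(manual_readjustment(p, list()), p)
  q <- manual_readjustment(p, list(gas_f_gain = 9))
  expect_equal(unname(q["gas_f_gain"]), 9)
  expect_equal(unname(q["sol_f_gain"]), 1)
  expect_equal(attr(q, "overridden"), "gas_f_gain")
  expect_error(manual_readjustment(p, list(nope = 1)), "unknown parameter")
})

test_that("shipped overrides reproduce the packaged split-belt initial guess", {
  base <- load_params(path = system.file("extdata",
                                         "split_belt_base_synthetic.json",
                                         package = "gaitadapt"))
  guess <- load_params(path = system.file(
    "extdata", "split_belt_initial_guess_synthetic.json",
    package = "gaitadapt"))
  ov <- jsonlite::fromJSON(system.file("extdata",
                                       "manual_overrides_synthetic.json",
                                       package = "gaitadapt"))
  adj <- manual_readjustment(base$controller$params, ov)
  expect_equal(as.numeric(adj), as.numeric(guess$controller$params),
               tolerance = 1e-7)
  # overrides change exactly the named entries
  changed <- names(base$controller$params)[
    abs(base$controller$params - guess$controller$params) > 1e-12]
  expect_setequal(changed, names(ov))
})
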