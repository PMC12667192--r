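# Stride-level analysis pipeline on constructed fixtures with known
# ground truth.

test_that("step metrics recover prescribed step lengths, times and SLA", {
  ev <- make_events(10, d_fast = 0.5, d_slow = 0.6)
  calcn <- make_calcn(ev, l_fast = 0.4, l_slow = 0.6)
  sm <- step_metrics(ev, calcn)
  expect_true(all(abs(sm$l_fast - 0.4) < 1e-9))
  expect_true(all(abs(sm$l_slow - 0.6) < 1e-9))
  expect_true(all(abs(sm$d_fast - 0.5) < 1e-9))
  expect_true(all(abs(sm$d_slow - 0.6) < 1e-9))
  expect_true(all(abs(sm$sla - (-0.2)) < 1e-9))
  # SVA from the same records: (0.8 - 1.0) / 1.8
  expect_true(all(abs(sm$sva - (-0.2 / 1.8)) < 1e-9))
  # equal step lengths give zero SLA
  calcn0 <- make_calcn(ev, l_fast = 0.5, l_slow = 0.5)
  sm0 <- step_metrics(ev, calcn0)
  expect_true(all(abs(sm0$sla) < 1e-12))
  # the first gait cycle is excluded
  sm_all <- step_metrics(ev, calcn, exclude_first = FALSE)
  expect_equal(nrow(sm_all), nrow(sm) + 1L)
})

test_that("step metrics reject sparse or non-alternating events", {
  ev <- make_events(5)
  expect_error(step_metrics(ev[ev$leg == "fast", ], make_calcn(ev)),
               "at least 2")
  bad <- ev
  bad <- bad[!(bad$leg == "slow" & bad$type == "HS" &
                 abs(bad$time - sort(bad$time[bad$leg == "slow" &
                                               bad$type == "HS"])[3]) < 1e-9), ]
  expect_error(step_metrics(bad, make_calcn(ev)), "alternating")
})

test_that("decomposition baselines: symmetric gait gives 0 deg and 0.5", {
  g <- make_symmetric_gait(n_strides = 8)
  dec <- decomposition(g$limb, g$events)
  expect_true(all(abs(dec$co_diff) < 0.1))
  expect_true(all(abs(dec$phasing - 0.5) < 0.01))
})

test_that("decomposition recovers an imposed phase shift", {
  g <- make_symmetric_gait(n_strides = 8, stride_t = 1.0)
  # re-shift the fast signal: fast(t) = slow(t - 0.3 strides)
  w <- 2 * pi
  g$limb$fast <- 20 * cos(w * (g$limb$time - 0.5) - pi - 0.3 * 2 * pi)
  dec <- decomposition(g$limb, g$events, n_resample = 200L)
  expect_true(all(abs(dec$phasing - 0.3) <= 1 / 200 + 1e-9))
})

test_that("center of oscillation is the HS/TO limb-angle mean", {
  # limb angle +10 at HS, -10 at TO -> CO = 0
  tt <- seq(0, 10, by = 0.005)
  limb <- data.frame(time = tt,
                     fast = 10 * cos(2 * pi * tt),
                     slow = 10 * cos(2 * pi * tt - pi))
  ev <- data.frame(time = c(1, 1.5, 1.5, 2, 2, 2.5, 2.5, 3),
                   leg = c("fast", "fast", "slow", "slow",
                           "fast", "fast", "slow", "slow"),
                   type = rep(c("HS", "TO"), 4))
  dec <- decomposition(limb, ev)
  expect_true(all(abs(dec$co_fast) < 1e-6))
})

test_that("exponential fit recovers parameters", {
  s <- 1:60
  y <- 0.48 - (-0.11) * exp(-s / 8)
  fit <- fit_exponential(y, s)
  expect_equal(fit$a, 0.48, tolerance = 1e-6)
  expect_equal(fit$b, -0.11, tolerance = 1e-6)
  expect_equal(fit$c, 8, tolerance = 1e-5)
  # constant series: b ~ 0, a ~ mean
  fc <- fit_exponential(rep(0.3, 20))
  expect_equal(fc$a, 0.3, tolerance = 1e-8)
  expect_lt(abs(fc$b), 1e-6)
})

test_that("exponential fit rate estimate is robust to noise", {
  set.seed(7)
  reps <- 100
  rel_err <- replicate(reps, {
    s <- 1:80
    y <- 0.48 - (-0.11) * exp(-s / 8) + rnorm(80, 0, 0.01)
    fit <- fit_exponential(y, s)
    abs(fit$c - 8) / 8
  })
  expect_lt(median(rel_err), 0.2)
})

test_that("stride averaging drops indices covered by fewer than 2 runs", {
  r1 <- rep(1, 10); r2 <- rep(2, 10); r3 <- rep(3, 11)
  out <- stride_average(list(r1, r2, r3))
  expect_equal(length(out$mean), 10L)
  expect_equal(out$mean, rep(2, 10))
  out2 <- stride_average(list(rep(1, 10), rep(2, 11), rep(3, 11)))
  expect_equal(length(out2$mean), 11L)
  expect_equal(out2$mean[11], 2.5)
  expect_equal(out2$n[11], 2L)
  expect_error(stride_average(list(r1)), "at least 2")
})

test_that("waveform comparison: NCC and RMSE behave as defined", {
  x <- resample_cycle(seq(0, 1, length.out = 500),
                      sin(2 * pi * seq(0, 1, length.out = 500)))
  expect_equal(length(x), 101L)
  same <- waveform_compare(x, x)
  expect_equal(same$ncc, 1)
  expect_equal(same$rmse, 0)
  off <- waveform_compare(x + 5, x)
  expect_equal(off$rmse, 5)
  expect_equal(off$ncc, 1)
  flip <- waveform_compare(-x, x)
  expect_equal(flip$ncc, -1)
  flat <- waveform_compare(rep(2, 101), x)
  expect_true(flat$flagged)
  expect_true(is.na(flat$ncc))
})

test_that("EA/LA windows", {
  y <- 1:10
  w <- windows(y, 3)
  expect_equal(w$ea, 2)
  expect_equal(w$la, 9)
  expect_equal(windows(1:3, 3)$ea, 2)
  expect_error(windows(1:2, 3), "exceeds")
})

test_that("peak activations: per-stride smoothed maxima", {
  tt <- seq(0, 5, by = 0.01)
  act <- matrix(0.1, length(tt), 14)
  # muscle 3 (IL left): burst to 0.8 within each stride; single-sample
  # spike to 1.0 that smoothing must suppress
  act[, 3] <- 0.1 + 0.7 * (sin(2 * pi * tt)^20)
  act[250, 3] <- 1.0
  ev <- data.frame(time = c(0.5, 1.5, 2.5, 3.5, 4.5), leg = "fast",
                   type = "HS")
  tr <- make_traj()
  tr$time <- tt; tr$act <- act; tr$events <- ev
  pk <- peak_activations(tr, "fast", smooth_s = 0.05)
  expect_equal(nrow(pk), 4L)
  expect_true(all(abs(pk[, "IL_l"] - max(pk[, "IL_l"])) < 0.2))
  expect_true(all(pk[, "IL_l"] < 0.9))     # spike suppressed
  expect_true(all(abs(pk[, "TA_r"] - 0.1) < 1e-9))
})
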