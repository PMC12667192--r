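# Cerebellar forward model: closed-form pieces against hand arithmetic
# and a finite-difference oracle.

test_that("step velocity and asymmetry follow their definitions", {
  expect_equal(step_velocity(0.5, 0.5), 1.0)
  expect_equal(step_velocity(0, 0.6), 0)
  expect_error(step_velocity(0.5, 0), "d must be > 0")
  # homogeneity: scaling l and d together leaves SV unchanged
  for (f in c(0.5, 2, 10)) {
    expect_equal(step_velocity(0.4 * f, 0.55 * f), step_velocity(0.4, 0.55))
  }

  expect_equal(step_velocity_asymmetry(0.8, 0.8), 0)
  expect_equal(step_velocity_asymmetry(0.9, 0.6), 0.2)
  expect_equal(step_velocity_asymmetry(0.6, 0.9),
               -step_velocity_asymmetry(0.9, 0.6))
  expect_error(step_velocity_asymmetry(0.5, -0.5), "zero")
})

test_that("prediction error is a half squared difference", {
  expect_equal(prediction_error(0.3, 0.3), 0)
  expect_equal(prediction_error(0, 0.2), 0.02)
  expect_equal(prediction_error(0.1, 0.4), prediction_error(0.4, 0.1))
})

# independent oracle: central finite differences of e(SVA(sv_slow, sv_fast))
fd_gradients <- function(sv_slow, sv_fast, sva_pred, h = 1e-6) {
  e_of <- function(ss, sf) {
    sva <- (sf - ss) / (sf + ss)
    0.5 * (sva_pred - sva)^2
  }
  list(
    d_slow = (e_of(sv_slow + h, sv_fast) - e_of(sv_slow - h, sv_fast)) / (2 * h),
    d_fast = (e_of(sv_slow, sv_fast + h) - e_of(sv_slow, sv_fast - h)) / (2 * h)
  )
}

test_that("closed-form error gradients match the finite-difference oracle", {
  g <- error_gradients(0.6, 0.9, 0)
  fd <- fd_gradients(0.6, 0.9, 0)
  expect_equal(g$d_slow, fd$d_slow, tolerance = 1e-8)
  expect_equal(g$d_fast, fd$d_fast, tolerance = 1e-8)
  # signs: with zero prediction and a faster fast leg, slowing the slow leg
  # further increases the error gradient asymmetrically
  expect_lt(g$d_slow, 0)
  expect_gt(g$d_fast, 0)
  # stationary when prediction matches observation
  sva <- step_velocity_asymmetry(0.9, 0.6)
  g0 <- error_gradients(0.6, 0.9, sva)
  expect_equal(g0$d_slow, 0, tolerance = 1e-12)
  expect_equal(g0$d_fast, 0, tolerance = 1e-12)
})

test_that("gradient oracle holds over a parameter grid", {
  svs <- seq(0.2, 1.5, length.out = 8)
  preds <- seq(-0.5, 0.5, length.out = 5)
  worst <- 0
  for (ss in svs) for (sf in svs) for (p in preds) {
    g <- error_gradients(ss, sf, p)
    fd <- fd_gradients(ss, sf, p)
    ref <- max(abs(fd$d_slow), abs(fd$d_fast), 1e-3)
    worst <- max(worst,
                 abs(g$d_slow - fd$d_slow) / ref,
                 abs(g$d_fast - fd$d_fast) / ref)
  }
  expect_lt(worst, 1e-6)
})

test_that("heel-strike update applies the gradient-descent rules", {
  st <- cerebellum_state(alpha = 0.5, beta = 0.02)
  # first fast step: no update yet (no slow step observed)
  r <- on_heel_strike(st, list(leg = "fast", l = 0.45, d = 0.5), 0.3, 0.3)
  expect_false(r$updated)
  expect_equal(r$state$sva_pred, 0)
  # slow step completes the pair: SVA = 0.2 with these observations
  # fast SV = 0.45/0.5 = 0.9, slow SV = 0.36/0.6 = 0.6
  r <- on_heel_strike(r$state, list(leg = "slow", l = 0.36, d = 0.6),
                      0.3, 0.3)
  expect_true(r$updated)
  expect_equal(r$state$sva_pred, 0.1)  # 0 - 0.5 * (0 - 0.2)
  g <- error_gradients(0.6, 0.9, 0)
  expect_equal(r$t_slow, 0.3 - 0.02 * g$d_slow)
  expect_equal(r$t_fast, 0.3 - 0.02 * g$d_fast)

  # alpha = 0 freezes the prediction; beta = 0 freezes the thresholds
  st0 <- cerebellum_state(alpha = 0, beta = 0.02)
  r0 <- on_heel_strike(st0, list(leg = "fast", l = 0.45, d = 0.5), 0.3, 0.3)
  r0 <- on_heel_strike(r0$state, list(leg = "slow", l = 0.36, d = 0.6),
                       0.3, 0.3)
  expect_equal(r0$state$sva_pred, 0)
  expect_false(isTRUE(all.equal(r0$t_slow, 0.3)))

  stb <- cerebellum_state(alpha = 0.5, beta = 0)
  rb <- on_heel_strike(stb, list(leg = "fast", l = 0.45, d = 0.5), 0.3, 0.3)
  rb <- on_heel_strike(rb$state, list(leg = "slow", l = 0.36, d = 0.6),
                       0.3, 0.3)
  expect_equal(rb$t_slow, 0.3)
  expect_equal(rb$t_fast, 0.3)
})

test_that("thresholds are clamped at the floor and clamps are counted", {
  st <- cerebellum_state(alpha = 0, beta = 50)  # absurd rate to force clamp
  r <- on_heel_strike(st, list(leg = "fast", l = 0.45, d = 0.5), 0.05, 0.05)
  r <- on_heel_strike(r$state, list(leg = "slow", l = 0.36, d = 0.6),
                      0.05, 0.05)
  expect_gte(r$t_slow, r$state$t_floor)
  expect_gte(r$t_fast, r$state$t_floor)
  expect_gte(r$state$n_clamped, 1L)
})

test_that("symmetric observations leave prediction and thresholds alone", {
  st <- cerebellum_state(alpha = 0.1, beta = 0.05)
  t_s <- 0.35; t_f <- 0.35
  for (k in 1:50) {
    r <- on_heel_strike(st, list(leg = "fast", l = 0.5, d = 0.55), t_s, t_f)
    st <- r$state; t_s <- r$t_slow; t_f <- r$t_fast
    r <- on_heel_strike(st, list(leg = "slow", l = 0.5, d = 0.55), t_s, t_f)
    st <- r$state; t_s <- r$t_slow; t_f <- r$t_fast
  }
  expect_equal(st$sva_pred, 0)
  expect_equal(t_s, 0.35)
  expect_equal(t_f, 0.35)
})
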