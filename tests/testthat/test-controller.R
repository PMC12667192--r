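# Reflex controller: wiring resolution, law evaluation, state machine,
# delays, trunk PD.

test_that("free-parameter counts are 62 spinal + 2 thresholds", {
  p <- default_spinal_params()
  expect_length(p, 62L)
  ctrl <- spinal_controller(p)
  expect_equal(ctrl$n_free, 64L)
  expect_error(spinal_controller(p[-1]), "62")
  expect_error(spinal_controller(p, t_left = 0), "> 0")
})

test_that("wiring resolves parameters and rejects unknown names/kinds", {
  w <- default_wiring()
  p <- default_spinal_params()
  laws <- build_laws(w, p)
  expect_length(laws$gain, nrow(w))
  expect_true(all(laws$target %in% 0:13))
  w2 <- w; w2$gain[1] <- "no_such_param"
  expect_error(build_laws(w2, p), "unknown parameter")
  w3 <- w; w3$kind[2] <- "X"
  expect_error(build_laws(w3, p), "unknown law kind")
})

test_that("zero gains give the minimum excitation everywhere", {
  m <- build_default_model()
  p <- default_spinal_params(); p[] <- 0
  p[grep("_off_", names(p))] <- 2
  ctrl <- spinal_controller(p)
  u <- compute_excitations(m, ctrl, c("ES", "ES"), rep(0.5, 14),
                           rep(1, 14))
  expect_true(all(u == m$min_exc))
})

test_that("a single force-feedback law is gain * normalized force, clamped", {
  m <- build_default_model()
  p <- default_spinal_params(); p[] <- 0
  p[grep("_off_", names(p))] <- 2
  p["sol_f_l"] <- 0.8
  ctrl <- spinal_controller(p)
  fn <- rep(0, 14); fn[6] <- 0.5  # SOL left normalized force
  u <- compute_excitations(m, ctrl, c("ES", "ES"), fn, rep(1, 14))
  expect_equal(unname(u["SOL_l"]), 0.01 + 0.8 * 0.5)
  expect_equal(unname(u["SOL_r"]), 0.01)
  # outside its phase set the law contributes nothing
  u_sw <- compute_excitations(m, ctrl, c("SW", "SW"), fn, rep(1, 14))
  expect_equal(unname(u_sw["SOL_l"]), 0.01)
  # excitations never exceed 1
  fn[6] <- 50
  u_big <- compute_excitations(m, ctrl, c("ES", "ES"), fn, rep(1, 14))
  expect_true(all(u_big <= 1))
})

test_that("trunk PD: zero at target, extensors on forward lean, linear", {
  expect_equal(trunk_pd(-0.09, 0), 0)
  # forward lean (more negative tilt than target): positive signal,
  # which excites extensors (positive law gain) and inhibits the flexor
  s_fwd <- trunk_pd(-0.2, 0)
  expect_gt(s_fwd, 0)
  s_back <- trunk_pd(0.1, 0)
  expect_lt(s_back, 0)
  # linear in tilt error at fixed velocity
  e1 <- trunk_pd(-0.19, 0.05) - trunk_pd(-0.09, 0.05)
  e2 <- trunk_pd(-0.29, 0.05) - trunk_pd(-0.19, 0.05)
  expect_equal(e1, e2)
  # distributed through the wiring: forward lean raises GLU/HAM, not IL
  m <- build_default_model()
  ctrl <- spinal_controller()
  u_f <- compute_excitations(m, ctrl, c("ES", "SW"), rep(0, 14),
                             rep(0.8, 14), tilt = -0.25, load = c(1, 0))
  u_0 <- compute_excitations(m, ctrl, c("ES", "SW"), rep(0, 14),
                             rep(0.8, 14), tilt = -0.09, load = c(1, 0))
  expect_gt(u_f[["GLU_l"]], u_0[["GLU_l"]])
  expect_gt(u_f[["HAM_l"]], u_0[["HAM_l"]])
  expect_lte(u_f[["IL_l"]], u_0[["IL_l"]])
})

test_that("phase machine transitions follow the thresholds", {
  smp <- c(0.2, 0.15, 0.30)
  # heel strike resets to ES from anywhere
  expect_equal(update_phase("SW", 1, 0.5, 0.8, 0.2, 0, smp,
                            heel_strike = TRUE), "ES")
  # ES -> MS on contralateral unloading
  expect_equal(update_phase("ES", 0.1, 0.5, 0.9, 0.1, 0, smp), "MS")
  expect_equal(update_phase("ES", 0.1, 0.5, 0.9, 0.5, 0, smp), "ES")
  # MS -> PS exactly at the swing-initiation threshold
  expect_equal(update_phase("MS", 0.5 - 1e-9, 0.5, 0.9, 0.1, 0, smp), "MS")
  expect_equal(update_phase("MS", 0.5, 0.5, 0.9, 0.1, 0, smp), "PS")
  # PS -> SW on own unloading
  expect_equal(update_phase("PS", 0.6, 0.5, 0.1, 0.9, 0, smp), "SW")
  # SW -> LP once the limb swings forward past the angle threshold
  expect_equal(update_phase("SW", 0.8, 0.5, 0, 0.9, 0.35, smp), "LP")
  expect_equal(update_phase("SW", 0.8, 0.5, 0, 0.9, 0.1, smp), "SW")
})

test_that("phase sequence over a cycle visits ES,MS,PS,SW,LP in order", {
  smp <- c(0.2, 0.15, 0.30)
  # scripted sensor trajectory over one gait cycle
  t <- seq(0, 1.1, by = 0.01)
  load_ipsi <- ifelse(t < 0.65, 0.9, 0)
  load_contra <- ifelse(t < 0.1 | t > 0.55, 0.9, 0.05)
  limb <- ifelse(t < 0.9, -0.1, 0.4)
  ph <- "ES"; seen <- "ES"
  for (i in seq_along(t)) {
    ph <- update_phase(ph, t[i], 0.45, load_ipsi[i], load_contra[i],
                       limb[i], smp)
    if (ph != seen[length(seen)]) seen <- c(seen, ph)
  }
  expect_equal(seen, c("ES", "MS", "PS", "SW", "LP"))
})

test_that("delayed reads a buffer at t - delay", {
  buf <- list(t = seq(0, 1, by = 0.001),
              value = sin(2 * pi * seq(0, 1, by = 0.001)))
  expect_equal(delayed(buf, 0, 0.5), sin(pi), tolerance = 1e-9)
  # constant signal unaffected
  cb <- list(t = 0:10, value = rep(3, 11))
  expect_equal(delayed(cb, 0.02, 5), 3)
  # sine shifted by the delay
  expect_equal(delayed(buf, 0.02, 0.5), sin(2 * pi * 0.48),
               tolerance = 1e-4)
  # before warm-up: earliest sample
  expect_equal(delayed(buf, 0.5, 0.1), buf$value[1])
  expect_error(delayed(list(t = numeric(0), value = numeric(0)), 0, 1),
               "empty")
})

test_that("reflex-only run equals a cerebellum run with zero rates", {
  m <- build_default_model()
  ctrl <- spinal_controller()
  tr_off <- simulate_gait(m, ctrl, NULL, duration = 1.5)
  tr_zero <- simulate_gait(m, ctrl, cerebellum_state(alpha = 0, beta = 0),
                           duration = 1.5)
  expect_identical(tr_off$q, tr_zero$q)
  expect_identical(tr_off$events, tr_zero$events)
})

test_that("packaged wiring CSV round-trips to the default wiring", {
  w <- read_wiring()
  d <- default_wiring()
  expect_equal(w$target, d$target)
  expect_equal(w$gain, d$gain)
  expect_equal(w$phases, d$phases)
  laws_csv <- build_laws(w, default_spinal_params())
  laws_def <- build_laws(d, default_spinal_params())
  expect_equal(laws_csv, laws_def)
})
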