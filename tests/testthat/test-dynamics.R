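# Multibody dynamics, contact, and simulation-loop contracts.

# a controller that produces only the minimum excitation
zero_controller <- function() {
  p <- default_spinal_params()
  p[] <- 0
  p[grep("_off_", names(p))] <- 2  # length-feedback offsets out of reach
  spinal_controller(p, t_left = 0.5, t_right = 0.5)
}

# model with negligible muscles and no passive joint torques
passive_model <- function(gravity = 9.81) {
  cfg <- default_model_config()
  for (mn in names(cfg$muscles)) cfg$muscles[[mn]][1] <- 1e-6
  for (jn in names(cfg$limits)) {
    cfg$limits[[jn]]$k <- 1e-9
    cfg$limits[[jn]]$damping <- 0
  }
  cfg$gravity <- gravity
  build_default_model(cfg)
}

test_that("model construction validates its configuration", {
  m <- build_default_model()
  expect_equal(nrow(m$muscles), 14L)
  expect_equal(length(initial_pose(m)), 9L)
  cfg <- default_model_config()
  cfg$segments$thigh$mass <- -1
  expect_error(build_default_model(cfg), "thigh\\$mass")
  cfg2 <- default_model_config()
  cfg2$muscles$SOL <- c(4000, 0.04, 0.26)
  expect_error(build_default_model(cfg2), "needs 7 values")
})

test_that("static standing supports approximately body weight", {
  m <- build_default_model()
  ctrl <- zero_controller()
  q <- initial_pose(m, hip_l = 0.02, knee_l = 0.05, ankle_l = 0,
                    hip_r = -0.02, knee_r = 0.05, ankle_r = 0, tilt = 0)
  init <- equilibrate_initial_state(m, ctrl, q)
  tr <- simulate_gait(m, ctrl, NULL, duration = 0.3,
                      belts = belt_config(0, 0), init = init)
  # vertical GRF over the settled interval ~ total weight
  n <- nrow(tr$extra$grf)
  fy <- tr$extra$grf[(n %/% 2):n, 1] + tr$extra$grf[(n %/% 2):n, 3]
  expect_equal(mean(fy), m$total_mass * 9.81, tolerance = 0.1)
})

test_that("contact forces follow the Hunt-Crossley law", {
  m <- build_default_model()
  r <- m$seg[["r_sphere"]]
  # sphere above the belt: zero force
  f0 <- contact_force(m, y_center = r + 0.01)
  expect_equal(unname(f0), c(0, 0))
  # static penetration: undamped normal term k * d^n
  d <- 0.003
  f <- contact_force(m, y_center = r - d)
  expect_equal(unname(f[["fy"]]), 2.5e6 * d^1.5, tolerance = 1e-12)
  expect_equal(unname(f[["fx"]]), 0)
  # foot stationary, belt moving backward: friction drags the foot back
  fb <- contact_force(m, y_center = r - d, vx = 0, belt_speed = 1)
  expect_lt(fb[["fx"]], 0)
  # normal force never negative (strong separation velocity)
  fs <- contact_force(m, y_center = r - d, vy = 10)
  expect_gte(fs[["fy"]], 0)
})

test_that("gravity-free flight conserves COM velocity", {
  m <- passive_model(gravity = 0)
  ctrl <- zero_controller()
  q <- initial_pose(m); q[2] <- q[2] + 1  # airborne
  init <- equilibrate_initial_state(m, ctrl, q)
  init$qd[1] <- 0.3; init$qd[2] <- 0.1
  tr <- simulate_gait(m, ctrl, NULL, duration = 0.5,
                      belts = belt_config(0, 0), init = init)
  coms <- t(vapply(seq_len(nrow(tr$q)),
                   function(i) unlist(forward_kinematics(m, tr$q[i, ])$com),
                   numeric(2)))
  vx <- diff(coms[, 1]) / diff(tr$time)
  vy <- diff(coms[, 2]) / diff(tr$time)
  expect_lt(max(abs(vx - vx[1])), 1e-6)
  expect_lt(max(abs(vy - vy[1])), 1e-6)
})

test_that("a rigid-leg pendulum swings at the closed-form frequency", {
  m <- passive_model()
  ctrl <- zero_controller()
  # pelvis and all joints fixed except the left hip; straight left leg
  q <- c(0, 2.0, 0, 0.08, 0, 0, 0.4, 0.5, 0)  # airborne, small hip angle
  init <- equilibrate_initial_state(m, ctrl, q)
  set <- sim_settings(dt = 1e-4, fixed_dofs = c(1, 2, 3, 5, 6, 7, 8, 9))
  tr <- simulate_gait(m, ctrl, NULL, duration = 6,
                      belts = belt_config(0, 0), settings = set,
                      init = init)
  expect_equal(tr$stop_reason, "completed")
  # closed-form compound pendulum about the hip (straight leg, knee =
  # ankle = 0): distances of segment COMs from the hip
  s <- m$seg
  dat <- rbind(
    c(s[["m_thigh"]], s[["com_thigh"]], s[["I_thigh"]]),
    c(s[["m_shank"]], s[["L_thigh"]] + s[["com_shank"]], s[["I_shank"]]),
    c(s[["m_foot"]],
      sqrt((s[["L_thigh"]] + s[["L_shank"]] - s[["comy_foot"]])^2 +
             s[["comx_foot"]]^2), s[["I_foot"]]))
  I_hip <- sum(dat[, 3] + dat[, 1] * dat[, 2]^2)
  mgd <- sum(dat[, 1] * 9.81 * dat[, 2])
  omega <- sqrt(mgd / I_hip)
  # measured frequency from zero crossings of the hip angle
  hip <- tr$q[, 4] - mean(tr$q[, 4])
  cross <- which(diff(sign(hip)) != 0)
  period <- 2 * mean(diff(tr$time[cross]))
  expect_equal(2 * pi / period, omega, tolerance = 0.01)
})

test_that("trajectories self-converge as dt is halved", {
  m <- passive_model()
  ctrl <- zero_controller()
  q <- c(0, 2.0, 0, 0.3, 0.4, 0.1, -0.2, 0.6, -0.1)
  init <- equilibrate_initial_state(m, ctrl, q)
  fixed <- c(1, 2, 3)
  end_state <- function(dt) {
    tr <- simulate_gait(m, ctrl, NULL, duration = 1,
                        belts = belt_config(0, 0),
                        settings = sim_settings(dt = dt, fixed_dofs = fixed),
                        init = init)
    tr$q[nrow(tr$q), 4:9]
  }
  e1 <- max(abs(end_state(4e-4) - end_state(2e-4)))
  e2 <- max(abs(end_state(2e-4) - end_state(1e-4)))
  expect_lt(e2, e1)
  expect_lt(e2, 5e-3)
})

test_that("simulation is deterministic and early-stops on falls", {
  m <- build_default_model()
  ctrl <- zero_controller()
  tr1 <- simulate_gait(m, ctrl, NULL, duration = 3,
                       belts = belt_config(0.5, 0.5))
  tr2 <- simulate_gait(m, ctrl, NULL, duration = 3,
                       belts = belt_config(0.5, 0.5))
  expect_identical(tr1$q, tr2$q)
  expect_identical(tr1$events, tr2$events)
  # a passive model released with no controller falls and stops early
  expect_equal(tr1$stop_reason, "fell")
  expect_lt(tr1$t_end, 3)
})

test_that("mirrored model with swapped belts walks the mirrored path", {
  m <- build_default_model()
  ctrl <- spinal_controller()  # symmetric parameters
  qA <- initial_pose(m)
  qB <- qA; qB[4:6] <- qA[7:9]; qB[7:9] <- qA[4:6]
  iA <- equilibrate_initial_state(m, ctrl, qA, phases = c("ES", "MS"))
  iB <- equilibrate_initial_state(m, ctrl, qB, phases = c("MS", "ES"))
  trA <- simulate_gait(m, ctrl, NULL, duration = 0.8,
                       belts = belt_config(1.0, 0.5), init = iA,
                       phases0 = c("ES", "MS"), elapsed0 = c(0.05, 0.4))
  trB <- simulate_gait(m, ctrl, NULL, duration = 0.8,
                       belts = belt_config(0.5, 1.0), init = iB,
                       phases0 = c("MS", "ES"), elapsed0 = c(0.4, 0.05))
  n <- min(nrow(trA$q), nrow(trB$q))
  expect_lt(max(abs(trA$q[1:n, 4:6] - trB$q[1:n, 7:9])), 1e-5)
  expect_lt(max(abs(trA$q[1:n, 7:9] - trB$q[1:n, 4:6])), 1e-5)
})
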