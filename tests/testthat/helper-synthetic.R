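# Synthetic fixtures built in code: event logs, foot trajectories, limb
# angles and summary trajectories with known ground truth.

# Alternating heel-strike/toe-off event log. Step times d_fast (contra->fast
# HS) and d_slow; toe-off a fixed fraction after the own HS.
make_events <- function(n_strides, d_fast = 0.55, d_slow = 0.55,
                        to_frac = 0.65, t0 = 0.5) {
  stride <- d_fast + d_slow
  ev <- list()
  for (s in seq_len(n_strides + 1L)) {
    t_fast <- t0 + (s - 1) * stride
    t_slow <- t_fast + d_slow
    ev[[length(ev) + 1L]] <- data.frame(
      time = c(t_fast, t_fast + to_frac * stride,
               t_slow, t_slow + to_frac * stride),
      leg = c("fast", "fast", "slow", "slow"),
      type = c("HS", "TO", "HS", "TO"))
  }
  ev <- do.call(rbind, ev)
  ev[order(ev$time), ]
}

# Piecewise-linear calcaneus AP positions that hit prescribed step lengths
# at each heel strike: at a fast HS the fast foot leads by l_fast, at the
# following slow HS the slow foot leads by l_slow.
make_calcn <- function(events, l_fast = 0.5, l_slow = 0.5) {
  hs <- events[events$type == "HS", ]
  hs <- hs[order(hs$time), ]
  tt <- seq(min(hs$time) - 0.1, max(hs$time) + 0.1, by = 0.01)
  # anchor positions at HS times, interpolate in between
  xf <- numeric(nrow(hs)); xs <- numeric(nrow(hs))
  xref <- 0
  for (i in seq_len(nrow(hs))) {
    if (hs$leg[i] == "fast") {
      xf[i] <- xref + l_fast / 2; xs[i] <- xref - l_fast / 2
    } else {
      xs[i] <- xref + l_slow / 2; xf[i] <- xref - l_slow / 2
    }
  }
  data.frame(
    time = tt,
    fast = approx(hs$time, xf, xout = tt, rule = 2)$y,
    slow = approx(hs$time, xs, xout = tt, rule = 2)$y)
}

# Mirror-symmetric sinusoidal limb angles: the two legs are identical up
# to a half-stride shift; amplitude in degrees. Events are placed so that
# the limb angle at HS is +amp*cos(phi0) and at TO its mirror, giving a
# zero center of oscillation.
make_symmetric_gait <- function(n_strides = 12, stride_t = 1.1, amp = 20,
                                dt = 0.002, t0 = 0.5) {
  t_end <- t0 + (n_strides + 2) * stride_t
  tt <- seq(0, t_end, by = dt)
  w <- 2 * pi / stride_t
  fast <- amp * cos(w * (tt - t0))
  slow <- amp * cos(w * (tt - t0) - pi)   # half-stride shift
  # fast HS at limb angle peak (t0 + k*stride), TO half a period later at
  # the trough: CO = (amp + (-amp))/2 = 0 for both legs.
  ev <- list()
  for (s in seq_len(n_strides + 1L)) {
    tf <- t0 + (s - 1) * stride_t
    ev[[length(ev) + 1L]] <- data.frame(
      time = c(tf, tf + 0.5 * stride_t,
               tf + 0.5 * stride_t, tf + stride_t),
      leg = c("fast", "fast", "slow", "slow"),
      type = c("HS", "TO", "HS", "TO"))
  }
  ev <- do.call(rbind, ev); ev <- ev[order(ev$time), ]
  ev <- ev[ev$time <= t_end, ]
  list(limb = data.frame(time = tt, fast = fast, slow = slow), events = ev)
}

# Summary-only trajectory for objective tests.
make_traj <- function(t_end = 80, t_des = 80, met = 300, act3 = 2,
                      ub_over = 0.5, ankle = 10, knee = 50,
                      comx = c(0.01, 0.012, 0.011, 0.013, 0.011),
                      n_muscles = 14L) {
  gait_trajectory(time = NULL, events = data.frame(),
                  t_end = t_end, t_des = t_des,
                  met_rate_mean = met, act3_int = act3,
                  n_muscles = n_muscles, ub_time_over = ub_over,
                  ankle_P2_int = ankle, knee_T_int = knee,
                  comx_hs_ref = comx,
                  stop_reason = if (t_end >= t_des) "completed" else "fell")
}
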