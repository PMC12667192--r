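# Tiered treadmill objective: a survival tier that rewards staying on the
# treadmill for the full duration, and, once that is met, a composite of
# effort, upper-body motion, joint-range penalties, and treadmill-position
# drift.

#' Objective weights
#'
#' Default weights of the composite treadmill objective. The terms carry
#' different units, so magnitudes are not importance rankings.
#'
#' @param w_ub upper-body (pelvis tilt velocity) penalty weight.
#' @param w_pos treadmill position drift weight.
#' @param w_met metabolic rate weight (per W).
#' @param w_act cubed-activation weight.
#' @param w_ankle ankle range penalty weight (per deg^2 s).
#' @param w_knee knee limit torque weight (per N m s).
#' @export
objective_weights <- function(w_ub = 0.05, w_pos = 100, w_met = 0.001,
                              w_act = 20, w_ankle = 0.1, w_knee = 0.01) {
  w <- list(w_ub = w_ub, w_pos = w_pos, w_met = w_met, w_act = w_act,
            w_ankle = w_ankle, w_knee = w_knee)
  if (any(unlist(w) < 0)) stop("objective_weights: weights must be >= 0")
  structure(w, class = "objective_weights")
}

#' Ankle range penalty
#'
#' Zero inside `[a_min, a_max]`, linear distance to the nearer bound
#' outside. Units are degrees; the default admissible range is
#' [-60, 60] deg.
#'
#' @param angle ankle angle(s) in degrees.
#' @param a_min,a_max admissible range in degrees.
#' @export
ankle_penalty <- function(angle, a_min = -60, a_max = 60) {
  ifelse(angle < a_min, a_min - angle,
         ifelse(angle > a_max, angle - a_max, 0))
}

#' Evaluate the tiered treadmill objective on a trajectory
#'
#' Tier 1 (`J_t`): 0 if the run lasted the desired duration `t_des`,
#' otherwise `500000 / t_end`, so earlier failures cost more. Only when
#' `J_t = 0` is the composite evaluated:
#' `J = J_eff + w_ub * J_ub + J_dofs + w_pos * J_pos` with
#' effort `J_eff = w_met * Edot_mean + w_act * (1/M) int sum a_i^3 dt`,
#' upper-body penalty `J_ub = 100 *` time (s) with |pelvis tilt velocity|
#' above 10 deg/s (config-switchable to a one-shot penalty of 100),
#' joint penalty `J_dofs = w_ankle * int (P_L^2 + P_R^2) dt +
#' w_knee * int (T_L + T_R) dt` with the ankle penalty of
#' [ankle_penalty()] and the passive knee limit torque `T`, and
#' position drift `J_pos = |COMx_HS3 - COMx_HSend|` between the third and
#' last heel strike of the reference (fast) leg.
#'
#' @param traj a `gait_trajectory` (see [gait_trajectory()]): requires
#'   fields `t_end`, and the accumulated measures `met_rate_mean` (W),
#'   `act3_int` (integral of the cubed-activation sum, s), `n_muscles`,
#'   `ub_time_over` (s above the tilt-velocity threshold),
#'   `ankle_P2_int` (deg^2 s), `knee_T_int` (N m s), and `comx_hs_ref`
#'   (AP whole-body COM at each reference-leg heel strike, m).
#' @param weights an [objective_weights()].
#' @param t_des desired duration in s.
#' @param ub_mode "integral" (default; 100 per second above threshold) or
#'   "oneshot" (flat 100 if ever above).
#' @return object of class `objective_breakdown` with J, J_t, J_eff,
#'   J_ub, J_dofs, J_pos, tier, t_end, t_des.
#' @export
objective_evaluate <- function(traj, weights = objective_weights(),
                               t_des = 80,
                               ub_mode = c("integral", "oneshot")) {
  ub_mode <- match.arg(ub_mode)
  stopifnot(inherits(traj, "gait_trajectory"))
  t_end <- traj$t_end
  # completion judged to half an output sample
  done <- isTRUE(abs(t_end - t_des) <= traj$dt_out / 2) || t_end >= t_des
  J_t <- if (done) 0 else 500000 / t_end
  br <- list(J_t = J_t, J_eff = NA_real_, J_ub = NA_real_,
             J_dofs = NA_real_, J_pos = NA_real_,
             t_end = t_end, t_des = t_des, tier = 1L)
  if (J_t > 0) {
    br$J <- J_t
    return(structure(br, class = "objective_breakdown"))
  }
  J_eff <- weights$w_met * traj$met_rate_mean +
    weights$w_act * traj$act3_int / traj$n_muscles
  J_ub <- if (ub_mode == "integral") 100 * traj$ub_time_over
          else 100 * as.numeric(traj$ub_time_over > 0)
  J_dofs <- weights$w_ankle * traj$ankle_P2_int +
    weights$w_knee * traj$knee_T_int
  comx <- traj$comx_hs_ref
  if (length(comx) < 3) {
    # too few reference heel strikes for the drift term: fall back to the
    # survival tier with a diagnostic score
    warning("objective_evaluate: fewer than 3 reference heel strikes; ",
            "falling back to tier-1 score")
    br$J_t <- 500000 / t_end
    br$J <- br$J_t
    return(structure(br, class = "objective_breakdown"))
  }
  J_pos <- abs(comx[3] - comx[length(comx)])
  J <- J_eff + weights$w_ub * J_ub + J_dofs + weights$w_pos * J_pos
  structure(list(J = J, J_t = 0, J_eff = J_eff, J_ub = J_ub,
                 J_dofs = J_dofs, J_pos = J_pos,
                 t_end = t_end, t_des = t_des, tier = 2L),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  if (x$tier == 1L) {
    cat(sprintf("objective: tier 1 (failed run), J = J_t = %.6g (t_end = %.2f s of %.2f s)\n",
                x$J, x$t_end, x$t_des))
  } else {
    cat(sprintf("objective: tier 2, J = %.6g (J_eff %.4g, J_ub %.4g, J_dofs %.4g, J_pos %.4g)\n",
                x$J, x$J_eff, x$J_ub, x$J_dofs, x$J_pos))
  }
  invisible(x)
}

#' Construct a gait trajectory container
#'
#' Container for a simulated (or stored) trajectory: sampled time series,
#' the event log, and the accumulated measures consumed by the objective
#' and the analysis pipeline. Normally produced by [simulate_gait()];
#' exposed so stored trajectories and synthetic fixtures can be scored.
#'
#' @param time sample times (s).
#' @param q,qd matrices (samples x 9) of generalized coordinates and
#'   velocities; may be NULL for summary-only trajectories.
#' @param act matrix (samples x muscles) of activations, or NULL.
#' @param events data.frame(time, leg, type).
#' @param t_end end of integration (s).
#' @param t_des requested duration (s).
#' @param met_rate_mean time-average whole-body metabolic rate (W).
#' @param act3_int integral over time of the summed cubed activations (s).
#' @param n_muscles number of muscles M.
#' @param ub_time_over time (s) with |pelvis tilt velocity| > 10 deg/s.
#' @param ankle_P2_int integral of squared ankle penalties (deg^2 s).
#' @param knee_T_int integral of knee limit torques (N m s).
#' @param comx_hs_ref whole-body AP COM (m) at each reference-leg HS.
#' @param dt_out output sampling interval (s).
#' @param stop_reason "completed", "fell", or "drifted".
#' @param extra named list of engine extras (GRFs, foot positions, ...).
#' @export
gait_trajectory <- function(time, q = NULL, qd = NULL, act = NULL,
                            events, t_end, t_des,
                            met_rate_mean, act3_int, n_muscles = 14L,
                            ub_time_over, ankle_P2_int, knee_T_int,
                            comx_hs_ref, dt_out = 0.01,
                            stop_reason = "completed", extra = list()) {
  stopifnot(t_end > 0, n_muscles >= 1)
  structure(list(time = time, q = q, qd = qd, act = act, events = events,
                 t_end = t_end, t_des = t_des,
                 met_rate_mean = met_rate_mean, act3_int = act3_int,
                 n_muscles = n_muscles, ub_time_over = ub_time_over,
                 ankle_P2_int = ankle_P2_int, knee_T_int = knee_T_int,
                 comx_hs_ref = comx_hs_ref, dt_out = dt_out,
                 stop_reason = stop_reason, extra = extra),
            class = "gait_trajectory")
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf(
    "gait_trajectory: t_end = %.2f s (%s), %d events, %d samples\n",
    x$t_end, x$stop_reason, NROW(x$events),
    if (is.null(x$time)) 0L else length(x$time)))
  invisible(x)
}
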