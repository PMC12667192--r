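# Simulation driver: initial-state equilibration, the forward simulation
# loop (engine), cerebellar coupling at heel-strike events, and the
# trajectory container glue for the analysis pipeline.

#' Default initial walking pose
#'
#' Legs split (left forward), slight forward trunk lean; the vertical
#' position is set so the lowest contact sphere just touches the belt.
#'
#' @param model a `gait_model`.
#' @param hip_l,hip_r,knee_l,knee_r,ankle_l,ankle_r joint angles (rad).
#' @param tilt pelvis tilt (rad).
#' @return generalized coordinate vector (9).
#' @export
initial_pose <- function(model, hip_l = 0.32, knee_l = 0.10,
                         ankle_l = -0.05, hip_r = -0.12, knee_r = 0.18,
                         ankle_r = 0.05, tilt = -0.06) {
  q <- c(0, 1.0, tilt, hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r)
  k <- cpp_fk(model, q)
  low <- min(k$legs[[1]]$heel[2], k$legs[[1]]$toe[2],
             k$legs[[2]]$heel[2], k$legs[[2]]$toe[2])
  r <- model$seg[["r_sphere"]]
  # settle with enough penetration to carry about half body weight on
  # the leading foot from the first step
  pen <- (0.5 * model$total_mass * 9.81 / model$contact[["k"]])^(1 / 1.5)
  q[2] <- q[2] - (low - r) - pen
  q
}

#' Two-pass equilibration of the initial muscle states
#'
#' Pass 1 equilibrates the fibers at the minimal activation; the reflex
#' laws are then evaluated on the resulting lengths and forces to obtain
#' initial activations; pass 2 re-equilibrates the fibers at those
#' activations.
#'
#' @param model a `gait_model`.
#' @param ctrl a [spinal_controller()].
#' @param q initial pose (9).
#' @param qd initial velocities (9).
#' @param phases initial phase per leg.
#' @return list(q, qd, a, lce, excitations).
#' @export
equilibrate_initial_state <- function(model, ctrl, q, qd = rep(0, 9),
                                      phases = c("ES", "MS")) {
  lmt <- cpp_mtu_lengths(model, q)
  a_min <- rep(model$min_exc, 14)
  lce1 <- vapply(1:14, function(i)
    cpp_muscle_equilibrium(model, i, a_min[i], lmt[i]), numeric(1))
  fnorm <- vapply(1:14, function(i) {
    eps <- (lmt[i] - lce1[i] * model$muscles[i, 2]) / model$muscles[i, 3] - 1
    if (eps <= 0) 0 else min((eps / 0.04)^2, 10)
  }, numeric(1))
  u <- compute_excitations(model, ctrl, phases, fnorm, lce1,
                           tilt = q[3], tiltvel = qd[3], load = c(1, 1))
  a2 <- pmin(pmax(unname(u), model$min_exc), 1)
  lce2 <- vapply(1:14, function(i)
    cpp_muscle_equilibrium(model, i, a2[i], lmt[i]), numeric(1))
  list(q = q, qd = qd, a = a2, lce = lce2, excitations = u)
}

# map engine leg index (0 left, 1 right) to fast/slow by belt speeds;
# with tied belts the left leg is "fast" by convention.
leg_labels <- function(belts) {
  if (belts$right > belts$left) c("slow", "fast") else c("fast", "slow")
}

#' Run a split-belt walking simulation
#'
#' Forward-dynamic simulation of the reflex-controlled model, optionally
#' closed through the cerebellar layer: at every heel strike the
#' triggering leg's step observation (length, time) is fed to
#' [on_heel_strike()], which updates the shared SVA prediction and both
#' legs' swing-initiation thresholds. Runs until `duration` or early
#' stop (vertical COM below 85 % of initial, or AP COM drift beyond
#' 10 m).
#'
#' @param model a `gait_model`.
#' @param ctrl a [spinal_controller()].
#' @param cerebellum a [cerebellum_state()], or NULL for the reflex-only
#'   model.
#' @param duration simulated time (s).
#' @param belts a [belt_config()].
#' @param settings a [sim_settings()].
#' @param init optional initial state from [equilibrate_initial_state()];
#'   default pose otherwise.
#' @param phases0 initial phase per leg (left, right).
#' @param elapsed0 initial time since each leg's (virtual) last heel
#'   strike (s); staggers the two legs within the cycle.
#' @return a [gait_trajectory()] with engine extras (per-step table,
#'   cerebellum log, final state, thresholds).
#' @export
simulate_gait <- function(model, ctrl, cerebellum = NULL, duration = 80,
                          belts = belt_config(), settings = sim_settings(),
                          init = NULL, phases0 = c("ES", "MS"),
                          elapsed0 = c(0.05, 0.4)) {
  stopifnot(inherits(model, "gait_model"),
            inherits(ctrl, "spinal_controller"), duration > 0)
  if (is.null(init)) {
    init <- equilibrate_initial_state(model, ctrl, initial_pose(model),
                                      phases = phases0)
  }
  ea <- controller_engine_args(ctrl)
  labels <- leg_labels(belts)
  cereb_log <- NULL
  cb <- NULL
  if (!is.null(cerebellum)) {
    stopifnot(inherits(cerebellum, "cerebellum_state"))
    state <- cerebellum
    thr <- c(ctrl$t_left, ctrl$t_right)  # engine order: left, right
    # t_slow / t_fast in cerebellum terms
    i_fast <- which(labels == "fast"); i_slow <- which(labels == "slow")
    log_env <- new.env()
    log_env$rows <- list()
    cb <- function(leg0, l, d) {
      lab <- labels[leg0 + 1L]
      res <- on_heel_strike(state, list(leg = lab, l = l, d = d),
                            t_slow = thr[i_slow], t_fast = thr[i_fast])
      state <<- res$state
      thr[i_slow] <<- res$t_slow; thr[i_fast] <<- res$t_fast
      log_env$rows[[length(log_env$rows) + 1L]] <-
        c(leg = leg0, l = l, d = d,
          sva = if (is.finite(state$sva_obs)) state$sva_obs else NA_real_,
          sva_pred = state$sva_pred,
          error = if (is.finite(state$error)) state$error else NA_real_,
          t_slow = res$t_slow, t_fast = res$t_fast)
      c(thr[1], thr[2])
    }
  }
  ip <- match(phases0, PHASES) - 1L
  raw <- cpp_simulate(model, ea$laws, ea$sm_left, ea$sm_right,
                      ea$pd_kp, ea$pd_kd, ea$pd_ref, ea$t_thresholds,
                      duration, c(belts$left, belts$right),
                      settings, init$q, init$qd, init$a, init$lce,
                      as.integer(ip), elapsed0, cb)
  if (!is.null(cerebellum) && length(log_env$rows)) {
    cereb_log <- as.data.frame(do.call(rbind, log_env$rows))
    cereb_log$leg <- labels[cereb_log$leg + 1L]
  }
  events <- data.frame(time = raw$ev_time,
                       leg = labels[raw$ev_leg + 1L],
                       type = c("HS", "TO", "fallback")[raw$ev_type + 1L])
  steps <- data.frame(time = raw$st_time,
                      leg = labels[raw$st_leg + 1L],
                      l = raw$st_l, d = raw$st_d)
  stopr <- c("completed", "fell", "drifted", "nonfinite")[raw$stop_reason + 1]
  ref_is_left <- labels[1] == "fast"
  comx_ref <- if (ref_is_left) raw$comx_hs_left else raw$comx_hs_right
  extra <- list(grf = raw$grf, calcn_x = raw$calcn_x,
                limb_deg = raw$limb_deg, phase = raw$phase,
                exc = raw$exc, steps = steps,
                labels = labels,
                thresholds = raw$thresholds,
                final = list(q = raw$final_q, qd = raw$final_qd,
                             a = raw$final_a, lce = raw$final_lce,
                             phase = PHASES[raw$final_phase + 1L],
                             elapsed = raw$final_elapsed),
                cereb_log = NULL)
  tr <- gait_trajectory(
    time = raw$time, q = raw$q, qd = raw$qd, act = raw$act,
    events = events, t_end = raw$t_end, t_des = duration,
    met_rate_mean = raw$met_rate_mean, act3_int = raw$act3_int,
    n_muscles = 14L, ub_time_over = raw$ub_time_over,
    ankle_P2_int = raw$ankle_P2_int, knee_T_int = raw$knee_T_int,
    comx_hs_ref = comx_ref, dt_out = settings$out_dt,
    stop_reason = stopr, extra = extra)
  # attach the cerebellum log assembled by the callback
  if (!is.null(cerebellum)) {
    tr$extra$cereb_log <- cereb_log
  }
  tr
}

#' Per-stride table from a simulated trajectory
#'
#' Builds the stride records from the engine's per-heel-strike step
#' observations (first gait cycle excluded): step lengths, times,
#' velocities, SLA and SVA per stride (a fast step paired with the
#' following slow step).
#'
#' @param traj a [simulate_gait()] trajectory.
#' @return data.frame as in [step_metrics()].
#' @export
traj_stride_table <- function(traj) {
  st <- traj$extra$steps
  if (is.null(st) || nrow(st) < 4)
    stop("traj_stride_table: too few steps recorded")
  fast_idx <- which(st$leg == "fast")
  recs <- lapply(fast_idx, function(i) {
    j <- i + 1L
    if (j > nrow(st) || st$leg[j] != "slow") return(NULL)
    data.frame(t_hs_fast = st$time[i], t_hs_slow = st$time[j],
               l_fast = st$l[i], l_slow = st$l[j],
               d_fast = st$d[i], d_slow = st$d[j])
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs) || nrow(recs) < 2)
    stop("traj_stride_table: too few strides")
  recs <- recs[-1L, , drop = FALSE]  # exclude first gait cycle
  recs$sv_fast <- recs$l_fast / recs$d_fast
  recs$sv_slow <- recs$l_slow / recs$d_slow
  recs$sla <- (recs$l_fast - recs$l_slow) / (recs$l_fast + recs$l_slow)
  recs$sva <- (recs$sv_fast - recs$sv_slow) / (recs$sv_fast + recs$sv_slow)
  cbind(stride = seq_len(nrow(recs)), recs)
}

#' Limb-angle table from a trajectory
#'
#' @param traj a recorded trajectory.
#' @return data.frame(time, fast, slow) of limb angles in degrees.
#' @export
traj_limb_angles <- function(traj) {
  lab <- traj$extra$labels
  ld <- traj$extra$limb_deg
  data.frame(time = traj$time,
             fast = ld[, which(lab == "fast")],
             slow = ld[, which(lab == "slow")])
}

#' Calcaneus AP-position table from a trajectory
#'
#' @param traj a recorded trajectory.
#' @return data.frame(time, fast, slow) in m.
#' @export
traj_calcn <- function(traj) {
  lab <- traj$extra$labels
  cx <- traj$extra$calcn_x
  data.frame(time = traj$time,
             fast = cx[, which(lab == "fast")],
             slow = cx[, which(lab == "slow")])
}

#' Write a trajectory to plain-text files
#'
#' Time series as CSV (header row, time in s) and the event log as JSON
#' lines `{time, leg, type}`; summary measures and the configuration
#' hash as a JSON sidecar.
#'
#' @param traj a trajectory.
#' @param dir output directory (created if needed).
#' @param config_hash hash string recorded in the sidecar.
#' @return dir, invisibly.
#' @export
write_trajectory <- function(traj, dir, config_hash = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(traj$time)) {
    ts <- data.frame(time = traj$time)
    if (!is.null(traj$q)) {
      qn <- c("pelvis_x", "pelvis_y", "pelvis_tilt",
              "hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")
      colnames(traj$q) <- qn
      ts <- cbind(ts, traj$q)
    }
    utils::write.csv(ts, file.path(dir, "timeseries.csv"),
                     row.names = FALSE)
  }
  con <- file(file.path(dir, "events.jsonl"), "w")
  if (nrow(traj$events)) {
    for (i in seq_len(nrow(traj$events))) {
      writeLines(jsonlite::toJSON(as.list(traj$events[i, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  close(con)
  summary <- list(t_end = traj$t_end, t_des = traj$t_des,
                  stop_reason = traj$stop_reason,
                  met_rate_mean = traj$met_rate_mean,
                  act3_int = traj$act3_int,
                  ub_time_over = traj$ub_time_over,
                  ankle_P2_int = traj$ankle_P2_int,
                  knee_T_int = traj$knee_T_int,
                  comx_hs_ref = traj$comx_hs_ref,
                  config_hash = config_hash)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
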