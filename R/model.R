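# Planar musculoskeletal model definition: segment inertial properties,
# seven Hill-type muscle-tendon units per leg with constant moment arms,
# Hunt-Crossley contact spheres, passive joint stops, and the treadmill
# belt configuration. All values live in one nested configuration and are
# flattened for the C++ engine.
#
# Coordinates: +x anterior, +y up, belt surface at y = 0. Generalized
# coordinates: pelvis AP/vertical translation and tilt (CCW positive),
# then hip (flexion +), knee (flexion +), ankle (dorsiflexion +) per leg,
# left leg first. Leg 0/left walks on the fast belt.

MUSCLE_NAMES <- c("HAM", "GLU", "IL", "VAS", "GAS", "SOL", "TA")

#' Default model configuration
#'
#' Segment masses, lengths and inertias approximate a 75 kg, 1.80 m adult
#' (head-arms-trunk lumped with the pelvis, lumbar joint locked at 8.5 deg
#' flexion so pelvis and trunk form one segment); muscle parameters follow
#' the established planar reflex-walking literature. All entries can be
#' overridden via the `config` argument of [build_default_model()].
#'
#' @return nested list of model parameters.
#' @export
default_model_config <- function() {
  list(
    segments = list(
      pelvis = list(mass = 53.5, inertia = 3.0, com = c(0.0, 0.35)),
      thigh = list(mass = 8.5, inertia = 0.15, length = 0.43, com = 0.19),
      shank = list(mass = 3.5, inertia = 0.055, length = 0.43, com = 0.19),
      foot = list(mass = 1.25, inertia = 0.007, com = c(0.05, -0.04),
                  heel = c(-0.045, -0.055), toe = c(0.16, -0.055),
                  radius = 0.025)
    ),
    lumbar_deg = 8.5,
    contact = list(stiffness = 2.5e6, exponent = 1.5, dissipation = 1.0,
                   friction = 0.9, v_transition = 0.1),
    # per joint: limit range (rad), exponential stop gain/width, damping
    limits = list(
      hip = list(lo = -0.7, hi = 1.9, k = 10, w = 0.03, damping = 1.0),
      knee = list(lo = 0.0, hi = 2.3, k = 30, w = 0.03, damping = 0.8),
      ankle = list(lo = -0.9, hi = 0.7, k = 5, w = 0.03, damping = 0.5)
    ),
    gravity = 9.81,
    min_excitation = 0.01,
    basal_rate_w_per_kg = 1.2,
    # reference joint angles at which l_mt = l_opt + l_slack
    qref = c(hip = 0.0, knee = 0.17, ankle = 0.0),
    muscles = list(
      #        Fmax  lopt lslack vmax  r_hip  r_knee r_ankle
      HAM = c(3000, 0.10, 0.31, 12, -0.07, 0.025, 0.000),
      GLU = c(1500, 0.11, 0.13, 12, -0.06, 0.000, 0.000),
      IL  = c(2000, 0.11, 0.10, 12, 0.05, 0.000, 0.000),
      VAS = c(6000, 0.08, 0.23, 12, 0.00, -0.042, 0.000),
      GAS = c(1500, 0.05, 0.40, 12, 0.00, 0.020, -0.050),
      SOL = c(4000, 0.04, 0.26, 6, 0.00, 0.000, -0.050),
      TA  = c( 800, 0.06, 0.24, 12, 0.00, 0.000, 0.040)
    )
  )
}

#' Build the planar split-belt walking model
#'
#' Validates the configuration and produces the flattened model object
#' consumed by the dynamics engine: a 9-DOF planar skeleton (pelvis-trunk
#' plus two three-segment legs on pin joints), 7 muscle-tendon units per
#' leg with the spanning pattern IL/GLU hip, HAM hip+knee, VAS knee, GAS
#' knee+ankle, SOL/TA ankle, and two Hunt-Crossley contact spheres per
#' foot.
#'
#' @param config optional nested list; entries override
#'   [default_model_config()] (modifyList semantics).
#' @return object of class `gait_model`.
#' @export
build_default_model <- function(config = list()) {
  cfg <- utils::modifyList(default_model_config(), config)
  # ---- validation ----
  chk_pos <- function(x, field) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      stop("model configuration error: field '", field,
           "' must be positive and finite")
  }
  for (s in c("pelvis", "thigh", "shank", "foot")) {
    if (is.null(cfg$segments[[s]]))
      stop("model configuration error: missing segment '", s, "'")
    chk_pos(cfg$segments[[s]]$mass, paste0("segments$", s, "$mass"))
    chk_pos(cfg$segments[[s]]$inertia, paste0("segments$", s, "$inertia"))
  }
  chk_pos(cfg$segments$thigh$length, "segments$thigh$length")
  chk_pos(cfg$segments$shank$length, "segments$shank$length")
  chk_pos(cfg$segments$foot$radius, "segments$foot$radius")
  if (length(cfg$muscles) != 7 ||
      !all(MUSCLE_NAMES %in% names(cfg$muscles)))
    stop("model configuration error: need the 7 muscles ",
         paste(MUSCLE_NAMES, collapse = ", "), " per leg")
  for (mn in MUSCLE_NAMES) {
    v <- cfg$muscles[[mn]]
    if (length(v) != 7)
      stop("model configuration error: muscles$", mn, " needs 7 values")
    chk_pos(v[1], paste0("muscles$", mn, "[Fmax]"))
    chk_pos(v[2], paste0("muscles$", mn, "[lopt]"))
    chk_pos(v[3], paste0("muscles$", mn, "[lslack]"))
    chk_pos(v[4], paste0("muscles$", mn, "[vmax]"))
    if (any(!is.finite(v[5:7])))
      stop("model configuration error: muscles$", mn, " moment arms")
  }
  # ---- flatten ----
  sg <- cfg$segments
  seg <- c(m_pelvis = sg$pelvis$mass, I_pelvis = sg$pelvis$inertia,
           comx_pelvis = sg$pelvis$com[1], comy_pelvis = sg$pelvis$com[2],
           m_thigh = sg$thigh$mass, I_thigh = sg$thigh$inertia,
           L_thigh = sg$thigh$length, com_thigh = sg$thigh$com,
           m_shank = sg$shank$mass, I_shank = sg$shank$inertia,
           L_shank = sg$shank$length, com_shank = sg$shank$com,
           m_foot = sg$foot$mass, I_foot = sg$foot$inertia,
           comx_foot = sg$foot$com[1], comy_foot = sg$foot$com[2],
           heelx = sg$foot$heel[1], heely = sg$foot$heel[2],
           toex = sg$foot$toe[1], toey = sg$foot$toe[2],
           r_sphere = sg$foot$radius)
  contact <- c(k = cfg$contact$stiffness, n = cfg$contact$exponent,
               c_d = cfg$contact$dissipation, mu = cfg$contact$friction,
               v_t = cfg$contact$v_transition)
  lim <- rbind(
    unlist(cfg$limits$hip[c("lo", "hi", "k", "w", "damping")]),
    unlist(cfg$limits$knee[c("lo", "hi", "k", "w", "damping")]),
    unlist(cfg$limits$ankle[c("lo", "hi", "k", "w", "damping")]))
  mus <- matrix(0, 14, 8)
  for (side in 0:1) {
    for (i in seq_along(MUSCLE_NAMES)) {
      mus[side * 7 + i, ] <- c(cfg$muscles[[MUSCLE_NAMES[i]]], side)
    }
  }
  total_mass <- sg$pelvis$mass +
    2 * (sg$thigh$mass + sg$shank$mass + sg$foot$mass)
  m <- list(seg = seg, contact = contact, limits = lim,
            grav = cfg$gravity, min_exc = cfg$min_excitation,
            basal_W = cfg$basal_rate_w_per_kg * total_mass,
            muscles = mus, qref = unname(cfg$qref),
            total_mass = total_mass,
            muscle_names = c(paste0(MUSCLE_NAMES, "_l"),
                             paste0(MUSCLE_NAMES, "_r")),
            config = cfg)
  class(m) <- "gait_model"
  m
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("gait_model: 9 DOF, %d muscles, total mass %.1f kg\n",
              nrow(x$muscles), x$total_mass))
  invisible(x)
}

#' Belt configuration
#'
#' @param left,right belt speeds in m/s (surface moves posteriorly).
#'   The main split-belt condition is left 1.0, right 0.5 (2:1).
#' @export
belt_config <- function(left = 1.0, right = 0.5) {
  if (left < 0 || right < 0) stop("belt_config: speeds must be >= 0")
  structure(list(left = left, right = right), class = "belt_config")
}

#' Numerical settings of the engine
#'
#' @param dt integration step (s). Semi-implicit Euler; 0.2 ms keeps the
#'   stiff contact-friction dynamics stable at treadmill loads.
#' @param out_dt output sampling interval (s).
#' @param hs_threshold heel-strike force threshold (N).
#' @param refractory heel-strike refractory period (s).
#' @param com_frac early stop when vertical COM drops below this fraction
#'   of its initial value.
#' @param drift_max early stop when |AP COM drift| exceeds this (m).
#' @param record keep full time series (default TRUE).
#' @param fixed_dofs indices (1-based) of coordinates to lock (testing).
#' @export
sim_settings <- function(dt = 2e-4, out_dt = 0.01, hs_threshold = 20,
                         refractory = 0.05, com_frac = 0.85,
                         drift_max = 10, record = TRUE,
                         fixed_dofs = integer(0)) {
  stopifnot(dt > 0, out_dt >= dt)
  list(dt = dt, out_dt = out_dt, hs_threshold = hs_threshold,
       refractory = refractory, com_frac = com_frac,
       drift_max = drift_max, record = record,
       fixed_dofs = as.integer(fixed_dofs))
}

#' Muscle-tendon lengths at a pose
#'
#' Constant-moment-arm path model: `l_mt = l_ref - sum_j r_j (q_j -
#' q_ref_j)` with `l_ref = l_opt + l_slack` at the reference pose.
#'
#' @param model a [build_default_model()] model.
#' @param q generalized coordinates (9).
#' @return named vector of 14 muscle-tendon lengths (m).
#' @export
mtu_lengths <- function(model, q) {
  out <- cpp_mtu_lengths(model, q)
  names(out) <- model$muscle_names
  out
}

#' Forward kinematics of the planar model
#'
#' @param model a `gait_model`.
#' @param q generalized coordinates (9).
#' @return list with hip point, whole-body COM, pelvis COM, and per-leg
#'   knee/ankle/heel/toe/calcaneus points and limb angle (rad, forward
#'   positive), left leg first.
#' @export
forward_kinematics <- function(model, q) {
  cpp_fk(model, q)
}

#' Advance one Hill-type muscle one time step
#'
#' First-order activation dynamics followed by the fiber update from the
#' tendon/fiber force balance (elastic tendon, closed-form inverted
#' force-velocity curve).
#'
#' @param model a `gait_model`.
#' @param muscle muscle index 1..14 (left HAM..TA, then right).
#' @param excitation neural excitation in [0, 1] (clamped from below at
#'   the configured minimum).
#' @param state list(a, lce_norm).
#' @param mtu_length muscle-tendon length (m).
#' @param dt time step (s).
#' @return list(a, lce_norm, f_tendon, vtilde).
#' @export
muscle_step <- function(model, muscle, excitation, state, mtu_length, dt) {
  cpp_muscle_step(model, as.integer(muscle), excitation, state$a,
                  state$lce_norm, mtu_length, dt)
}

#' Isometric muscle fiber equilibrium
#'
#' Normalized fiber length solving the isometric tendon/fiber force
#' balance at a given activation and muscle-tendon length (bisection).
#'
#' @inheritParams muscle_step
#' @param a activation.
#' @export
muscle_equilibrium <- function(model, muscle, a, mtu_length) {
  cpp_muscle_equilibrium(model, as.integer(muscle), a, mtu_length)
}

#' Hunt-Crossley contact force of one sphere on a belt
#'
#' Normal force `k * pen^n * (1 + 1.5 c pen_dot)` clamped at zero;
#' tangential smooth Coulomb friction against the sphere velocity
#' relative to the belt surface (which moves posteriorly at the belt
#' speed).
#'
#' @param model a `gait_model`.
#' @param y_center sphere center height (m).
#' @param vx,vy sphere center velocity (m/s).
#' @param belt_speed belt speed (m/s, >= 0).
#' @return named vector fx, fy (N) acting on the foot.
#' @export
contact_force <- function(model, y_center, vx = 0, vy = 0, belt_speed = 0) {
  cpp_sphere_force(model, y_center, vx, vy, belt_speed)
}

#' Whole-body metabolic rate
#'
#' Muscle-level energetics: per muscle `a * Fmax * vmax * phi(vbar)` with
#' a shortening-heat curve of the Minetti-Alexander type plus a basal
#' rate proportional to body mass; lengthening is costed at the
#' isometric level.
#'
#' @param model a `gait_model`.
#' @param a activations (14).
#' @param vtilde normalized fiber velocities (14, shortening negative).
#' @return metabolic power in W.
#' @export
metabolic_rate <- function(model, a, vtilde = rep(0, 14)) {
  cpp_metabolic_rate(model, a, vtilde)
}
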