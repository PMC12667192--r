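# Reflex-based spinal gait controller: a per-leg phase state machine
# (early stance ES, mid-stance MS, pre-swing PS, swing SW, landing
# preparation LP), delayed muscle force/length feedback laws, trunk PD
# balance control and constant feedforward excitations. The controller is
# declarative: a wiring table names, for every reflex law, its target and
# source, phase set, neural delay tier, and the free parameter holding
# its gain/offset. The swing-initiation thresholds t (one per leg, the
# delay after the leg's own heel strike at which mid-stance ends) are the
# parameters the cerebellum adapts.

PHASES <- c("ES", "MS", "PS", "SW", "LP")
LAW_KINDS <- c(F = 0L, L = 1L, C = 2L, PD = 3L)

# neural delay tier by source signal (distance along the nerves)
DELAY_TIER <- c(HAM = 0.005, GLU = 0.005, IL = 0.005, VAS = 0.010,
                GAS = 0.020, SOL = 0.020, TA = 0.020, PD = 0.005)

#' Default spinal controller parameters
#'
#' Named vector of the 62 free spinal parameters (31 per leg, suffix
#' `_l`/`_r`): reflex gains and offsets, constants, trunk-PD gains and
#' target, and the three state-machine thresholds. Values are plausible
#' hand-tuned defaults in the spirit of the classic reflex-walking
#' controller; optimized parameter sets replace them.
#'
#' @return named numeric vector of length 62.
#' @export
default_spinal_params <- function() {
  per_leg <- c(
    sol_f = 1.1, sol_f_ps = 0.3, gas_f = 1.1,
    gas_l = 0.3, gas_l_off = 1.0,
    vas_f = 1.0, vas_c = 0.09, vas_c_lp = 0.08,
    ta_l = 1.1, ta_l_off = 0.71, ta_sol_f = 0.4, ta_c_sw = 0.25,
    ham_pd = 1.0, glu_pd = 1.0, il_pd = 0.8,
    il_c_ps = 0.25, il_c_sw = 0.15, il_l = 0.5, il_l_off = 0.9,
    il_ham_l = 0.4,
    glu_c_sw = 0.05, glu_c_lp = 0.1, ham_c_sw = 0.05,
    ham_f_lp = 0.65, glu_f_lp = 0.4,
    pd_kp = 2.0, pd_kd = 0.3, pd_ref = -0.09,
    load_es_ms = 0.2, load_ps_sw = 0.15, sw_lp_angle = 0.30
  )
  c(stats::setNames(per_leg, paste0(names(per_leg), "_l")),
    stats::setNames(per_leg, paste0(names(per_leg), "_r")))
}

# wiring table: one record per reflex law. gain/offset columns name
# parameters (resolved against the parameter vector); sign applies to the
# gain. Targets/sources without side suffix are instantiated per leg.
default_wiring_per_leg <- function() {
  W <- function(target, kind, source, gain, sign, offset, phases, loadw) {
    data.frame(target = target, kind = kind, source = source,
               gain = gain, sign = sign, offset = offset,
               phases = phases, loadw = loadw,
               stringsAsFactors = FALSE)
  }
  rbind(
    W("SOL", "F", "SOL", "sol_f", 1, "0", "ES,MS,PS", 0),
    W("SOL", "F", "SOL", "sol_f_ps", 1, "0", "PS", 0),
    W("GAS", "F", "GAS", "gas_f", 1, "0", "ES,MS,PS", 0),
    W("GAS", "L", "GAS", "gas_l", 1, "gas_l_off", "PS", 0),
    W("VAS", "F", "VAS", "vas_f", 1, "0", "ES,MS", 0),
    W("VAS", "C", "", "vas_c", 1, "0", "ES,MS", 0),
    W("VAS", "C", "", "vas_c_lp", 1, "0", "LP", 0),
    W("TA", "L", "TA", "ta_l", 1, "ta_l_off", "ES,MS,PS,SW,LP", 0),
    W("TA", "F", "SOL", "ta_sol_f", -1, "0", "ES,MS,PS", 0),
    W("TA", "C", "", "ta_c_sw", 1, "0", "SW", 0),
    W("HAM", "PD", "", "ham_pd", 1, "0", "ES,MS", 1),
    W("GLU", "PD", "", "glu_pd", 1, "0", "ES,MS", 1),
    W("IL", "PD", "", "il_pd", -1, "0", "ES,MS", 1),
    W("IL", "C", "", "il_c_ps", 1, "0", "PS", 0),
    W("IL", "C", "", "il_c_sw", 1, "0", "SW", 0),
    W("IL", "L", "IL", "il_l", 1, "il_l_off", "PS,SW", 0),
    W("IL", "L", "HAM", "il_ham_l", -1, "0.85", "SW", 0),
    W("GLU", "C", "", "glu_c_sw", 1, "0", "SW", 0),
    W("GLU", "C", "", "glu_c_lp", 1, "0", "LP", 0),
    W("HAM", "C", "", "ham_c_sw", 1, "0", "SW", 0),
    W("HAM", "F", "HAM", "ham_f_lp", 1, "0", "LP", 0),
    W("GLU", "F", "GLU", "glu_f_lp", 1, "0", "LP", 0)
  )
}

#' The reflex wiring table
#'
#' One row per reflex law and leg: target muscle, law kind (F muscle
#' force feedback, L muscle length feedback, C constant, PD trunk
#' proportional-derivative), source signal, the named free parameter
#' providing the gain (with sign) and offset, active phase set, neural
#' delay (by source tier: hip 5 ms, knee 10 ms, ankle 20 ms) and whether
#' the contribution is weighted by the ipsilateral leg load.
#'
#' @return data.frame with one row per law instance (both legs).
#' @export
default_wiring <- function() {
  per <- default_wiring_per_leg()
  out <- lapply(c("l", "r"), function(s) {
    w <- per
    w$side <- s
    w$target <- paste0(w$target, "_", s)
    w$source <- ifelse(w$source == "", "", paste0(w$source, "_", s))
    pn <- function(col) ifelse(grepl("^[0-9.]+$", w[[col]]), w[[col]],
                               paste0(w[[col]], "_", s))
    w$gain <- pn("gain"); w$offset <- pn("offset")
    w
  })
  out <- do.call(rbind, out)
  src_mus <- sub("_[lr]$", "", out$source)
  out$delay <- ifelse(out$kind == "PD", DELAY_TIER[["PD"]],
                      ifelse(src_mus %in% names(DELAY_TIER),
                             DELAY_TIER[src_mus], 0.005))
  rownames(out) <- NULL
  out
}

#' Read a reflex wiring table from CSV
#'
#' The wiring is declarative and editable: one record per reflex law
#' with the same columns as [default_wiring()]. A copy of the default
#' table ships as `extdata/reflex_wiring.csv`.
#'
#' @param path CSV file; default the packaged copy.
#' @return wiring data.frame usable with [build_laws()] and
#'   [spinal_controller()].
#' @export
read_wiring <- function(path = system.file("extdata", "reflex_wiring.csv",
                                           package = "gaitadapt")) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "kind", "source", "gain", "sign", "offset",
            "phases", "loadw", "side", "delay")
  missing <- setdiff(need, names(w))
  if (length(missing))
    stop("wiring table missing column(s): ", paste(missing, collapse = ", "))
  w$source[is.na(w$source)] <- ""
  w
}

muscle_index <- function(name) {
  side <- sub("^.*_", "", name)
  mus <- sub("_[lr]$", "", name)
  i <- match(mus, MUSCLE_NAMES)
  if (any(is.na(i))) stop("unknown muscle: ", paste(name[is.na(i)],
                                                    collapse = ", "))
  i + ifelse(side == "r", 7L, 0L)
}

phase_mask <- function(phases) {
  vapply(strsplit(phases, ","), function(p) {
    p <- trimws(p)
    bad <- setdiff(p, PHASES)
    if (length(bad)) stop("unknown phase: ", paste(bad, collapse = ","))
    as.integer(sum(2^(match(p, PHASES) - 1L)))
  }, integer(1))
}

#' Resolve the wiring table against a parameter vector
#'
#' Substitutes parameter names with values and converts the table to the
#' flat law structure the engine consumes (0-based indices, phase
#' bitmask, delays in s).
#'
#' @param wiring a [default_wiring()]-style data.frame.
#' @param params named spinal parameter vector (see
#'   [default_spinal_params()]).
#' @return list of law vectors for the engine.
#' @export
build_laws <- function(wiring, params) {
  resolve <- function(x) {
    num <- suppressWarnings(as.numeric(x))
    miss <- is.na(num)
    if (any(miss)) {
      unknown <- setdiff(x[miss], names(params))
      if (length(unknown))
        stop("configuration error: unknown parameter(s) ",
             paste(unique(unknown), collapse = ", "))
      num[miss] <- params[x[miss]]
    }
    num
  }
  if (!all(wiring$kind %in% names(LAW_KINDS)))
    stop("configuration error: unknown law kind ",
         paste(setdiff(wiring$kind, names(LAW_KINDS)), collapse = ","))
  list(
    target = muscle_index(wiring$target) - 1L,
    kind = unname(LAW_KINDS[wiring$kind]),
    source = ifelse(wiring$source == "", 0L,
                    muscle_index(ifelse(wiring$source == "",
                                        "HAM_l", wiring$source)) - 1L),
    loadw = as.integer(wiring$loadw),
    pmask = phase_mask(wiring$phases),
    gain = wiring$sign * resolve(wiring$gain),
    offset = resolve(wiring$offset),
    delay = wiring$delay
  )
}

#' Assemble a spinal controller
#'
#' Bundles the wiring, the 62 spinal parameters, and the two
#' swing-initiation thresholds into the controller object used by
#' [simulate_gait()]. Asserts the free-parameter count: 62 spinal values
#' plus the two thresholds = 64 (a cerebellum adds its 2 rates for 66).
#'
#' @param params named spinal parameter vector.
#' @param t_left,t_right swing-initiation thresholds in s (delay from the
#'   leg's own heel strike to the mid-stance to pre-swing transition).
#' @param wiring optional custom wiring table.
#' @return object of class `spinal_controller`.
#' @export
spinal_controller <- function(params = default_spinal_params(),
                              t_left = 0.55, t_right = 0.55,
                              wiring = default_wiring()) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  if (length(params) != 62)
    stop("spinal_controller: expected 62 spinal parameters, got ",
         length(params))
  if (t_left <= 0 || t_right <= 0)
    stop("spinal_controller: thresholds t must be > 0")
  n_free <- length(params) + 2L
  stopifnot(n_free == 64L)
  structure(list(params = params, t_left = t_left, t_right = t_right,
                 wiring = wiring, n_free = n_free),
            class = "spinal_controller")
}

#' @export
print.spinal_controller <- function(x, ...) {
  cat(sprintf(
    "spinal_controller: %d free parameters (62 spinal + 2 thresholds), t = (%.3f, %.3f) s\n",
    x$n_free, x$t_left, x$t_right))
  invisible(x)
}

# split per-side helper vectors for the engine
controller_engine_args <- function(ctrl) {
  p <- ctrl$params
  list(
    laws = build_laws(ctrl$wiring, p),
    sm_left = unname(p[c("load_es_ms_l", "load_ps_sw_l", "sw_lp_angle_l")]),
    sm_right = unname(p[c("load_es_ms_r", "load_ps_sw_r", "sw_lp_angle_r")]),
    pd_kp = unname(p[c("pd_kp_l", "pd_kp_r")]),
    pd_kd = unname(p[c("pd_kd_l", "pd_kd_r")]),
    pd_ref = unname(p[c("pd_ref_l", "pd_ref_r")]),
    t_thresholds = c(ctrl$t_left, ctrl$t_right)
  )
}

#' Update a leg's gait phase
#'
#' One step of the per-leg state machine. Transitions: a heel strike
#' resets to ES; ES->MS when the contralateral leg unloads; MS->PS when
#' the time since the leg's own heel strike reaches the swing-initiation
#' threshold t (with an unloading fallback that prevents deadlock);
#' PS->SW when the leg itself unloads; SW->LP when the limb swings past
#' the forward-angle threshold.
#'
#' @param phase current phase, one of "ES","MS","PS","SW","LP".
#' @param elapsed time since the leg's own heel strike (s).
#' @param t_threshold swing-initiation threshold (s).
#' @param load_ipsi,load_contra leg loads as fraction of body weight.
#' @param limb_angle limb angle (rad, forward positive).
#' @param sm_params numeric (load_es_ms, load_ps_sw, sw_lp_angle).
#' @param heel_strike TRUE if a heel strike occurred this step.
#' @return new phase (character).
#' @export
update_phase <- function(phase, elapsed, t_threshold, load_ipsi,
                         load_contra, limb_angle,
                         sm_params = c(0.2, 0.15, 0.30),
                         heel_strike = FALSE) {
  ip <- match(phase, PHASES)
  if (is.na(ip)) stop("unknown phase: ", phase)
  np <- cpp_update_phase(ip - 1L, elapsed, t_threshold, load_ipsi,
                         load_contra, limb_angle, sm_params, heel_strike)
  PHASES[np + 1L]
}

#' Evaluate the reflex laws into muscle excitations
#'
#' Pure evaluation of the wiring at given (already delayed) sensor
#' values; the same primitive the simulation loop applies every step.
#'
#' @param model a `gait_model`.
#' @param ctrl a [spinal_controller()].
#' @param phases character 2-vector, phase per leg (left, right).
#' @param fnorm normalized tendon forces (14).
#' @param lnorm normalized fiber lengths (14).
#' @param tilt,tiltvel pelvis tilt (rad, CCW+) and velocity (rad/s).
#' @param load leg loads (2), fraction of body weight.
#' @return named excitation vector in [min_excitation, 1].
#' @export
compute_excitations <- function(model, ctrl, phases, fnorm, lnorm,
                                tilt = 0, tiltvel = 0, load = c(1, 1)) {
  ea <- controller_engine_args(ctrl)
  ip <- match(phases, PHASES) - 1L
  if (any(is.na(ip))) stop("unknown phase")
  u <- cpp_excitations(model, ea$laws, as.integer(ip), fnorm, lnorm,
                       tilt, tiltvel, load, ea$pd_kp, ea$pd_kd, ea$pd_ref)
  stats::setNames(u, model$muscle_names)
}

#' Trunk PD balance signal
#'
#' Forward-lean-positive proportional-derivative signal
#' `kp (theta_ref - tilt) - kd tiltvel`, distributed to the stance-leg
#' hip extensors (positive gain) and flexor (negative gain), weighted by
#' the leg load.
#'
#' @param tilt pelvis tilt (rad, CCW positive so forward lean is
#'   negative).
#' @param tiltvel tilt velocity (rad/s).
#' @param kp,kd PD gains.
#' @param target reference tilt (rad).
#' @export
trunk_pd <- function(tilt, tiltvel, kp = 2.0, kd = 0.3, target = -0.09) {
  kp * (target - tilt) - kd * tiltvel
}

#' Read a signal value at a delayed time
#'
#' Linear interpolation of a sampled signal buffer at `t - delay`;
#' before warm-up (t - delay earlier than the buffer) the earliest
#' sample is returned.
#'
#' @param buffer data.frame/list with numeric `t` and `value`.
#' @param delay neural delay (s, >= 0).
#' @param t current time (s).
#' @export
delayed <- function(buffer, delay, t) {
  if (length(buffer$t) == 0) stop("delayed: empty buffer")
  tq <- t - delay
  if (tq <= buffer$t[1]) return(buffer$value[1])
  stats::approx(buffer$t, buffer$value, xout = tq, rule = 2)$y
}
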