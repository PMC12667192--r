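# Cerebellar forward model: step-velocity-asymmetry prediction and
# gradient-descent adaptation of the swing-initiation thresholds.

#' Step velocity from step length and step time
#'
#' Step velocity is the ratio of step length to step time, computed per leg
#' at each of that leg's heel strikes.
#'
#' @param l step length in m (anterior-posterior distance between the two
#'   calcaneus centers of mass at the heel strike).
#' @param d step time in s (interval from the contralateral heel strike to
#'   the ipsilateral heel strike).
#' @return step velocity in m/s.
#' @export
#' @examples
#' step_velocity(0.5, 0.5) # 1
step_velocity <- function(l, d) {
  if (any(!is.finite(l)) || any(!is.finite(d)))
    stop("step_velocity: non-finite input")
  if (any(d <= 0)) stop("step_velocity: step time d must be > 0")
  l / d
}

#' Step velocity asymmetry
#'
#' Normalized interlimb difference of the step velocities,
#' \eqn{(SV_{fast} - SV_{slow}) / (SV_{fast} + SV_{slow})}. Zero for
#' symmetric walking; bounded in (-1, 1) for positive velocities. This is
#' the sensory outcome the cerebellar layer predicts and corrects.
#'
#' @param sv_fast,sv_slow step velocities (m/s) of the legs on the fast and
#'   slow belt.
#' @export
step_velocity_asymmetry <- function(sv_fast, sv_slow) {
  s <- sv_fast + sv_slow
  if (any(abs(s) < .Machine$double.eps)) {
    stop("step_velocity_asymmetry: SV_fast + SV_slow is zero")
  }
  (sv_fast - sv_slow) / s
}

#' Sensorimotor prediction error
#'
#' Squared difference between the predicted and the observed step velocity
#' asymmetry, \eqn{e = 0.5 (SVA_{pred} - SVA)^2}. Zero during tied-belt
#' walking where prediction and observation agree.
#'
#' @param sva_pred internal prediction of the SVA (dimensionless).
#' @param sva observed SVA.
#' @export
prediction_error <- function(sva_pred, sva) {
  0.5 * (sva_pred - sva)^2
}

#' Closed-form error gradients with respect to the step velocities
#'
#' Gradients of the prediction error (through the SVA definition) with
#' respect to the slow- and fast-leg step velocities. These drive the
#' motor update of the per-leg swing-initiation thresholds.
#'
#' @param sv_slow,sv_fast step velocities in m/s.
#' @param sva_pred current internal SVA prediction.
#' @return named list with `d_slow` and `d_fast`.
#' @export
error_gradients <- function(sv_slow, sv_fast, sva_pred) {
  s <- sv_slow + sv_fast
  if (any(abs(s) < .Machine$double.eps))
    stop("error_gradients: SV_slow + SV_fast is zero")
  num <- sv_slow - sv_fast + sva_pred * s
  list(
    d_slow = 2 * sv_fast * num / s^3,
    d_fast = -2 * sv_slow * num / s^3
  )
}

#' Create a cerebellum state
#'
#' The cerebellar layer keeps a single internal prediction of the step
#' velocity asymmetry, shared across both legs, plus the two rates that
#' govern adaptation: the learning rate `alpha` (how fast the internal
#' prediction tracks the observed SVA) and the adaptation rate `beta`
#' (how strongly the swing-initiation thresholds are driven down the error
#' gradient). The prediction starts at zero, corresponding to symmetric
#' tied-belt walking.
#'
#' @param alpha learning rate (>= 0); default 0.002.
#' @param beta adaptation rate (>= 0, shared across both legs);
#'   default 0.02.
#' @param error_metric "sva" (default) or "sla". With "sla" the prediction
#'   error is computed on step length asymmetry instead; the gradient
#'   update of the thresholds then uses step lengths in place of step
#'   velocities (experimental switch).
#' @param t_floor lower clamp on the swing thresholds after an update, in s.
#' @return object of class `cerebellum_state`.
#' @export
cerebellum_state <- function(alpha = 0.002, beta = 0.02,
                             error_metric = c("sva", "sla"),
                             t_floor = 0.010) {
  error_metric <- match.arg(error_metric)
  stopifnot(alpha >= 0, beta >= 0, t_floor > 0)
  structure(list(
    sva_pred = 0.0,
    alpha = alpha,
    beta = beta,
    error_metric = error_metric,
    t_floor = t_floor,
    sv_fast = NA_real_, sv_slow = NA_real_,
    l_fast = NA_real_, l_slow = NA_real_,
    error = NA_real_, sva_obs = NA_real_,
    n_updates = 0L,
    n_clamped = 0L
  ), class = "cerebellum_state")
}

#' @export
print.cerebellum_state <- function(x, ...) {
  cat("cerebellum_state: SVA_pred =", format(x$sva_pred, digits = 6),
      " alpha =", x$alpha, " beta =", x$beta,
      " updates =", x$n_updates, "\n")
  invisible(x)
}

#' Heel-strike update of the cerebellar state and swing thresholds
#'
#' Applied synchronously at every heel strike once at least one step has
#' been completed on each side. The triggering leg's step velocity is
#' refreshed from the observation, then (1) the internal prediction moves
#' toward the observed asymmetry at rate `alpha` and (2) both legs' swing
#' thresholds move down the error gradient with respect to their step
#' velocity at the shared rate `beta`. Thresholds are clamped from below
#' at `t_floor` to keep the phase state machine well-posed.
#'
#' @param state a [cerebellum_state()].
#' @param obs a list/row with fields `leg` ("fast" or "slow"), `l` (step
#'   length m) and `d` (step time s).
#' @param t_slow,t_fast current swing-initiation thresholds in s.
#' @return list with updated `state`, `t_slow`, `t_fast`, and `updated`
#'   (FALSE while step history is incomplete).
#' @export
on_heel_strike <- function(state, obs, t_slow, t_fast) {
  stopifnot(inherits(state, "cerebellum_state"))
  leg <- match.arg(obs$leg, c("fast", "slow"))
  if (!is.finite(obs$l) || !is.finite(obs$d) || obs$d <= 0)
    stop("on_heel_strike: invalid step observation")
  sv <- step_velocity(obs$l, obs$d)
  if (leg == "fast") {
    state$sv_fast <- sv; state$l_fast <- obs$l
  } else {
    state$sv_slow <- sv; state$l_slow <- obs$l
  }
  # No update until one completed step per leg has been observed.
  if (!is.finite(state$sv_fast) || !is.finite(state$sv_slow)) {
    return(list(state = state, t_slow = t_slow, t_fast = t_fast,
                updated = FALSE))
  }
  if (state$error_metric == "sva") {
    xf <- state$sv_fast; xs <- state$sv_slow
  } else {
    xf <- state$l_fast; xs <- state$l_slow
  }
  asym <- step_velocity_asymmetry(xf, xs)
  g <- error_gradients(xs, xf, state$sva_pred)
  state$error <- prediction_error(state$sva_pred, asym)
  state$sva_obs <- asym
  # Motor update first (uses the pre-update prediction), then the
  # prediction update; both use the latest per-leg observations.
  t_slow <- t_slow - state$beta * g$d_slow
  t_fast <- t_fast - state$beta * g$d_fast
  if (t_slow < state$t_floor || t_fast < state$t_floor)
    state$n_clamped <- state$n_clamped + 1L
  t_slow <- max(t_slow, state$t_floor)
  t_fast <- max(t_fast, state$t_floor)
  state$sva_pred <- state$sva_pred - state$alpha * (state$sva_pred - asym)
  state$n_updates <- state$n_updates + 1L
  list(state = state, t_slow = t_slow, t_fast = t_fast, updated = TRUE)
}
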