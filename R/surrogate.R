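# Surrogate stride map: a desk-scale stand-in for the full dynamics that
# maps the per-leg swing-initiation thresholds to step lengths and times,
# so the cerebellar closed loop and the analysis pipeline can be exercised
# in milliseconds instead of minutes.

#' Create a surrogate stride map
#'
#' Each leg's step length and step time respond affinely to its
#' swing-initiation threshold: `l = l0 + k_l * t`, `d = d0 + k_d * t`,
#' optionally with a cross-coupling term from the other leg's threshold
#' and Gaussian observation noise. Defaults emulate the early split-belt
#' gait at a 2:1 belt ratio: fast step about 0.37 m, slow step about
#' 0.51 m (SLA near -0.17), with threshold sensitivity of a few cm per
#' 100 ms. The coefficients are configuration, not claims about the
#' musculoskeletal dynamics.
#'
#' @param l0_fast,l0_slow baseline step lengths (m) at t = 0 offset from
#'   `t_ref`.
#' @param d0_fast,d0_slow baseline step times (s).
#' @param k_l_fast,k_l_slow step-length sensitivity to the own threshold
#'   (m per s of threshold).
#' @param k_d_fast,k_d_slow step-time sensitivity (s per s).
#' @param cross_l coupling of each leg's step length to the contralateral
#'   threshold (m per s); default 0.
#' @param t_ref reference threshold (s) at which the baselines apply.
#' @param noise_sd standard deviation of Gaussian noise added to step
#'   lengths and times (0 = deterministic).
#' @param t_range admissible threshold range (s); leaving it truncates a
#'   run with a flag.
#' @return object of class `stride_map`.
#' @export
stride_map <- function(l0_fast = 0.37, l0_slow = 0.51,
                       d0_fast = 0.52, d0_slow = 0.62,
                       k_l_fast = 0.5, k_l_slow = 0.5,
                       k_d_fast = 0.05, k_d_slow = 0.05,
                       cross_l = 0.0,
                       t_ref = 0.35,
                       noise_sd = 0.0,
                       t_range = c(0.01, 0.8)) {
  m <- list(l0_fast = l0_fast, l0_slow = l0_slow,
            d0_fast = d0_fast, d0_slow = d0_slow,
            k_l_fast = k_l_fast, k_l_slow = k_l_slow,
            k_d_fast = k_d_fast, k_d_slow = k_d_slow,
            cross_l = cross_l, t_ref = t_ref,
            noise_sd = noise_sd, t_range = t_range)
  # admissibility: positive l, d across the threshold range
  for (tt in t_range) {
    for (leg in c("fast", "slow")) {
      st <- surrogate_step(m, leg, tt, tt)
      if (st$l <= 0 || st$d <= 0)
        stop("stride_map: step length/time not positive over t_range")
    }
  }
  structure(m, class = "stride_map")
}

# One step of the map (noise-free part).
surrogate_step <- function(map, leg, t_own, t_other) {
  dt_own <- t_own - map$t_ref
  dt_other <- t_other - map$t_ref
  if (leg == "fast") {
    l <- map$l0_fast + map$k_l_fast * dt_own + map$cross_l * dt_other
    d <- map$d0_fast + map$k_d_fast * dt_own
  } else {
    l <- map$l0_slow + map$k_l_slow * dt_own + map$cross_l * dt_other
    d <- map$d0_slow + map$k_d_slow * dt_own
  }
  list(l = l, d = d)
}

#' Closed-loop surrogate simulation of the cerebellar adaptation
#'
#' Alternating fast/slow heel strikes are generated from the stride map at
#' the current thresholds and fed to [on_heel_strike()]; the thresholds
#' evolve stride by stride. Returns the per-stride table in the same
#' layout the full-dynamics analysis produces, plus the cerebellum log.
#'
#' @param map a [stride_map()].
#' @param cereb a [cerebellum_state()].
#' @param n_strides number of strides (one fast + one slow step each).
#' @param t_fast0,t_slow0 initial swing thresholds (s).
#' @param seed integer seed for the observation noise (ignored when
#'   `noise_sd = 0`).
#' @return list with `strides` (data.frame: stride, l_fast, l_slow,
#'   d_fast, d_slow, sv_fast, sv_slow, sla, sva), `log` (data.frame:
#'   stride, sva, sva_pred, error, t_slow, t_fast), final `state`,
#'   `t_fast`, `t_slow`, and `truncated` flag.
#' @export
simulate_strides <- function(map, cereb, n_strides,
                             t_fast0 = 0.35, t_slow0 = 0.35,
                             seed = 1L) {
  stopifnot(inherits(map, "stride_map"), inherits(cereb, "cerebellum_state"),
            n_strides >= 1)
  rng <- NULL
  if (map$noise_sd > 0) {
    rng <- local({ set.seed(as.integer(seed)); NULL })
  }
  t_fast <- t_fast0; t_slow <- t_slow0
  n <- as.integer(n_strides)
  strides <- data.frame(
    stride = seq_len(n), l_fast = NA_real_, l_slow = NA_real_,
    d_fast = NA_real_, d_slow = NA_real_,
    sv_fast = NA_real_, sv_slow = NA_real_,
    sla = NA_real_, sva = NA_real_
  )
  log <- data.frame(stride = seq_len(n), sva = NA_real_,
                    sva_pred = NA_real_, error = NA_real_,
                    t_slow = NA_real_, t_fast = NA_real_)
  truncated <- FALSE
  for (s in seq_len(n)) {
    out_of_range <- function(tt)
      tt < map$t_range[1] || tt > map$t_range[2]
    if (out_of_range(t_fast) || out_of_range(t_slow)) {
      truncated <- TRUE
      strides <- strides[seq_len(s - 1L), , drop = FALSE]
      log <- log[seq_len(s - 1L), , drop = FALSE]
      break
    }
    # fast heel strike ends the fast step, then slow heel strike.
    for (leg in c("fast", "slow")) {
      st <- surrogate_step(map, leg,
                           if (leg == "fast") t_fast else t_slow,
                           if (leg == "fast") t_slow else t_fast)
      if (map$noise_sd > 0) {
        st$l <- st$l + stats::rnorm(1, 0, map$noise_sd)
        st$d <- max(st$d + stats::rnorm(1, 0, map$noise_sd), 1e-3)
      }
      res <- on_heel_strike(cereb, list(leg = leg, l = st$l, d = st$d),
                            t_slow, t_fast)
      cereb <- res$state; t_slow <- res$t_slow; t_fast <- res$t_fast
      if (leg == "fast") {
        strides$l_fast[s] <- st$l; strides$d_fast[s] <- st$d
      } else {
        strides$l_slow[s] <- st$l; strides$d_slow[s] <- st$d
      }
    }
    strides$sv_fast[s] <- strides$l_fast[s] / strides$d_fast[s]
    strides$sv_slow[s] <- strides$l_slow[s] / strides$d_slow[s]
    strides$sla[s] <- (strides$l_fast[s] - strides$l_slow[s]) /
      (strides$l_fast[s] + strides$l_slow[s])
    strides$sva[s] <- (strides$sv_fast[s] - strides$sv_slow[s]) /
      (strides$sv_fast[s] + strides$sv_slow[s])
    log$sva[s] <- strides$sva[s]
    log$sva_pred[s] <- cereb$sva_pred
    log$error[s] <- if (is.finite(cereb$error)) cereb$error else NA_real_
    log$t_slow[s] <- t_slow; log$t_fast[s] <- t_fast
  }
  list(strides = strides, log = log, state = cereb,
       t_fast = t_fast, t_slow = t_slow, truncated = truncated)
}

#' Sweep learning and adaptation rates on the surrogate loop
#'
#' Runs the closed loop for every (alpha, beta) combination and summarizes
#' convergence: strides to half of the initial |SVA - SVA_pred| error,
#' and the SVA/SLA levels at the final stride.
#'
#' @param map a [stride_map()].
#' @param alphas,betas numeric grids of learning/adaptation rates.
#' @param n_strides strides per run.
#' @param t_fast0,t_slow0 initial thresholds (s).
#' @param seed passed to [simulate_strides()].
#' @return data.frame with columns alpha, beta, strides_to_half,
#'   final_sva, final_sla, sla_shift (final minus first stride).
#' @export
rate_sweep <- function(map, alphas, betas, n_strides = 200,
                       t_fast0 = 0.35, t_slow0 = 0.35, seed = 1L) {
  stopifnot(length(alphas) >= 1, length(betas) >= 1)
  grid <- expand.grid(alpha = alphas, beta = betas)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cereb <- cerebellum_state(alpha = grid$alpha[i], beta = grid$beta[i])
    run <- simulate_strides(map, cereb, n_strides,
                            t_fast0 = t_fast0, t_slow0 = t_slow0,
                            seed = seed)
    err <- abs(run$log$sva - run$log$sva_pred)
    half <- err[1] / 2
    idx <- which(err <= half)
    data.frame(
      alpha = grid$alpha[i], beta = grid$beta[i],
      strides_to_half = if (length(idx)) idx[1] else NA_integer_,
      final_sva = utils::tail(run$strides$sva, 1),
      final_sla = utils::tail(run$strides$sla, 1),
      sla_shift = utils::tail(run$strides$sla, 1) - run$strides$sla[1]
    )
  })
  do.call(rbind, out)
}
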