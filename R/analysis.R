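# Stride-level evaluation pipeline: step metrics and SLA/SVA series from
# heel-strike events, spatial/temporal decomposition of the adaptation,
# exponential adaptation fits, cross-run stride averaging, and waveform
# comparison against reference gait cycles.

#' Per-step and per-stride gait metrics from events and foot trajectories
#'
#' Computes step length (anterior-posterior distance between the two
#' calcaneus centers of mass at a heel strike), step time (interval from
#' the contralateral heel strike), and step velocity for every heel
#' strike, then assembles per-stride records with step length asymmetry
#' `SLA = (l_fast - l_slow) / (l_fast + l_slow)` and the analogous SVA.
#' A stride is anchored at a fast-leg heel strike and paired with the
#' following slow-leg step. The first gait cycle is excluded.
#'
#' @param events data.frame with columns `time`, `leg` ("fast"/"slow"),
#'   `type` ("HS"/"TO"); only HS rows are used here.
#' @param calcn data.frame with columns `time`, `fast`, `slow`: AP
#'   positions (m) of the two calcaneus COMs over time.
#' @param exclude_first logical; drop the first gait cycle (default TRUE).
#' @return data.frame with one row per stride: stride, t_hs_fast,
#'   t_hs_slow, l_fast, l_slow, d_fast, d_slow, sv_fast, sv_slow, sla,
#'   sva.
#' @export
step_metrics <- function(events, calcn, exclude_first = TRUE) {
  stopifnot(all(c("time", "leg", "type") %in% names(events)),
            all(c("time", "fast", "slow") %in% names(calcn)))
  hs <- events[events$type == "HS", , drop = FALSE]
  hs <- hs[order(hs$time), , drop = FALSE]
  if (sum(hs$leg == "fast") < 2 || sum(hs$leg == "slow") < 2)
    stop("step_metrics: need at least 2 heel strikes per leg")
  # events must alternate between legs
  runs <- rle(hs$leg)
  if (any(runs$lengths > 1)) {
    bad <- cumsum(runs$lengths)[which(runs$lengths > 1)[1]]
    stop(sprintf(
      "step_metrics: missing alternating heel strike near t = %.3f s",
      hs$time[bad]))
  }
  pos <- function(leg, t) {
    stats::approx(calcn$time, calcn[[leg]], xout = t, rule = 2)$y
  }
  # per-HS step length/time: leading (ipsilateral) foot minus trailing
  hs$l <- NA_real_; hs$d <- NA_real_
  for (i in seq_len(nrow(hs))[-1]) {
    leg <- hs$leg[i]; other <- if (leg == "fast") "slow" else "fast"
    hs$l[i] <- pos(leg, hs$time[i]) - pos(other, hs$time[i])
    hs$d[i] <- hs$time[i] - hs$time[i - 1]
  }
  fast_idx <- which(hs$leg == "fast" & is.finite(hs$l))
  recs <- lapply(fast_idx, function(i) {
    j <- i + 1L  # following slow HS
    if (j > nrow(hs) || hs$leg[j] != "slow" || !is.finite(hs$l[j]))
      return(NULL)
    data.frame(t_hs_fast = hs$time[i], t_hs_slow = hs$time[j],
               l_fast = hs$l[i], l_slow = hs$l[j],
               d_fast = hs$d[i], d_slow = hs$d[j])
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs) || nrow(recs) == 0)
    stop("step_metrics: no complete strides")
  if (exclude_first) recs <- recs[-1L, , drop = FALSE]
  if (nrow(recs) == 0) stop("step_metrics: no strides after exclusion")
  recs$sv_fast <- recs$l_fast / recs$d_fast
  recs$sv_slow <- recs$l_slow / recs$d_slow
  recs$sla <- (recs$l_fast - recs$l_slow) / (recs$l_fast + recs$l_slow)
  recs$sva <- (recs$sv_fast - recs$sv_slow) / (recs$sv_fast + recs$sv_slow)
  recs <- cbind(stride = seq_len(nrow(recs)), recs)
  rownames(recs) <- NULL
  recs
}

#' Spatial/temporal decomposition of interlimb coordination
#'
#' Spatial component: per-stride difference of the centers of oscillation
#' (slow minus fast), where a leg's center of oscillation is the mean of
#' its limb angle at its heel strike and at its toe-off. Temporal
#' component: per-stride limb phasing, the lag (as a fraction of the
#' stride) at the peak of the circular cross-correlation of the fast and
#' slow limb-angle trajectories, slow leg as reference. Baselines for
#' symmetric walking are 0 deg and 0.5.
#'
#' @param limb data.frame with columns `time`, `fast`, `slow`: limb
#'   angles in degrees (angle between the vertical and the vector from
#'   the pelvis COM to the calcaneus COM, positive forward).
#' @param events data.frame of `time`, `leg`, `type` with HS and TO rows.
#' @param n_resample samples per stride for the cross-correlation.
#' @return data.frame per stride: stride, co_fast, co_slow, co_diff
#'   (deg), phasing.
#' @export
decomposition <- function(limb, events, n_resample = 200L) {
  stopifnot(all(c("time", "fast", "slow") %in% names(limb)))
  ev <- events[order(events$time), , drop = FALSE]
  hs_slow <- ev$time[ev$leg == "slow" & ev$type == "HS"]
  if (length(hs_slow) < 2) stop("decomposition: need >= 2 slow heel strikes")
  ang <- function(leg, t) stats::approx(limb$time, limb[[leg]], xout = t,
                                        rule = 2)$y
  co_leg <- function(leg, t0, t1) {
    # own HS and TO inside [t0, t1)
    hs_t <- ev$time[ev$leg == leg & ev$type == "HS" &
                      ev$time >= t0 & ev$time < t1]
    to_t <- ev$time[ev$leg == leg & ev$type == "TO" &
                      ev$time >= t0 & ev$time < t1]
    if (!length(hs_t) || !length(to_t)) return(NA_real_)
    mean(c(ang(leg, hs_t[1]), ang(leg, to_t[1])))
  }
  out <- lapply(seq_len(length(hs_slow) - 1L), function(s) {
    t0 <- hs_slow[s]; t1 <- hs_slow[s + 1L]
    dur <- t1 - t0
    tt <- seq(t0, t1, length.out = n_resample + 1L)[seq_len(n_resample)]
    xs <- ang("slow", tt); xf <- ang("fast", tt)
    phasing <- NA_real_
    if (stats::sd(xs) > 1e-12 && stats::sd(xf) > 1e-12 &&
        dur > 10 * mean(diff(limb$time))) {
      zs <- (xs - mean(xs)) / stats::sd(xs)
      zf <- (xf - mean(xf)) / stats::sd(xf)
      # circular cross-correlation: lag by which fast must be shifted to
      # align with slow (slow is the reference)
      cc <- vapply(seq_len(n_resample) - 1L, function(k) {
        idx <- ((seq_len(n_resample) - 1L + k) %% n_resample) + 1L
        mean(zs * zf[idx])
      }, numeric(1))
      phasing <- (which.max(cc) - 1L) / n_resample
    } else {
      warning("decomposition: stride too short or flat; skipped")
    }
    data.frame(stride = s,
               co_fast = co_leg("fast", t0, t1),
               co_slow = co_leg("slow", t0, t1),
               phasing = phasing)
  })
  out <- do.call(rbind, out)
  out$co_diff <- out$co_slow - out$co_fast
  out[, c("stride", "co_fast", "co_slow", "co_diff", "phasing")]
}

#' Fit an exponential adaptation curve
#'
#' Nonlinear least squares fit of `y = a - b * exp(-s / c)` to a
#' per-stride series, where `s` is the stride number, `|b|` the amount of
#' adaptation and `c` the adaptation rate in strides. For a fixed rate
#' `c` the problem is linear in `(a, b)`, so the fit profiles the sum of
#' squares over `c` (multi-start log-spaced grid + local refinement),
#' which is robust and has no starting-value failures.
#'
#' @param y numeric series indexed by stride (s = 1, 2, ...).
#' @param s optional stride numbers (default `seq_along(y)`).
#' @param c_grid rate multi-start grid in strides.
#' @return object of class `exp_fit`: list(a, b, c, fitted, residuals,
#'   sse, converged).
#' @export
fit_exponential <- function(y, s = seq_along(y),
                            c_grid = exp(seq(log(0.5), log(500),
                                             length.out = 60))) {
  stopifnot(length(y) >= 5, length(y) == length(s))
  ab_for_c <- function(cc) {
    z <- exp(-s / cc)
    X <- cbind(1, -z)
    fit <- stats::lm.fit(X, y)
    list(a = fit$coefficients[1], b = fit$coefficients[2],
         sse = sum(fit$residuals^2))
  }
  sse_c <- vapply(c_grid, function(cc) ab_for_c(cc)$sse, numeric(1))
  i <- which.min(sse_c)
  lo <- c_grid[max(i - 1L, 1L)]; hi <- c_grid[min(i + 1L, length(c_grid))]
  opt <- stats::optimize(function(cc) ab_for_c(cc)$sse,
                         lower = lo, upper = hi, tol = 1e-12)
  # flat series: the profile is degenerate in c; report b ~ 0, a = mean
  best <- ab_for_c(opt$minimum)
  cc <- opt$minimum
  if (!is.finite(best$sse) || is.na(best$b)) {
    best <- list(a = mean(y), b = 0, sse = sum((y - mean(y))^2))
    cc <- NA_real_
  }
  fitted <- if (is.na(cc)) rep(best$a, length(y)) else
    best$a - best$b * exp(-s / cc)
  structure(list(a = unname(best$a), b = unname(best$b), c = cc,
                 fitted = fitted, residuals = y - fitted,
                 sse = best$sse, converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exp_fit: y = %.4g - (%.4g) * exp(-s/%.4g), SSE = %.3g\n",
              x$a, x$b, x$c, x$sse))
  invisible(x)
}

#' Stride-by-stride averaging across parallel runs
#'
#' Elementwise mean and standard deviation over runs. Runs may differ in
#' length; trailing stride indices covered by fewer than two runs are
#' dropped, so the average always pools at least two simulations.
#'
#' @param runs list of numeric vectors (one per run, indexed by stride).
#' @return list with `mean`, `sd`, `n` (runs contributing per stride).
#' @export
stride_average <- function(runs) {
  if (!is.list(runs) || length(runs) < 2)
    stop("stride_average: need at least 2 runs")
  lens <- lengths(runs)
  keep <- max(which(vapply(seq_len(max(lens)),
                           function(i) sum(lens >= i) >= 2, logical(1))))
  m <- vapply(seq_len(keep), function(i) {
    v <- unlist(lapply(runs, function(r) if (length(r) >= i) r[i] else NULL))
    c(mean(v), stats::sd(v), length(v))
  }, numeric(3))
  list(mean = m[1, ], sd = m[2, ], n = as.integer(m[3, ]))
}

#' Resample a gait cycle to percent stride
#'
#' Linear interpolation onto 101 evenly spaced points (0..100 % stride).
#'
#' @param t,y time (or phase) and signal samples over one cycle.
#' @param n number of points (default 101).
#' @export
resample_cycle <- function(t, y, n = 101L) {
  stats::approx(t, y, xout = seq(min(t), max(t), length.out = n))$y
}

#' Waveform similarity: normalized cross-correlation and RMSE
#'
#' Both cycles must be resampled to the same percent-stride grid (101
#' points; see [resample_cycle()]). NCC is the zero-lag normalized
#' (Pearson) cross-correlation coefficient; RMSE is in the signal's units
#' (degrees for joint angles). A constant signal leaves NCC undefined and
#' is flagged.
#'
#' @param sim,ref numeric vectors of equal length.
#' @return list(ncc, rmse, flagged).
#' @export
waveform_compare <- function(sim, ref) {
  stopifnot(length(sim) == length(ref), length(sim) >= 3)
  rmse <- sqrt(mean((sim - ref)^2))
  if (stats::sd(sim) < 1e-12 || stats::sd(ref) < 1e-12) {
    return(list(ncc = NA_real_, rmse = rmse, flagged = TRUE))
  }
  list(ncc = stats::cor(sim, ref), rmse = rmse, flagged = FALSE)
}

#' Early/late adaptation window summaries
#'
#' Means over the first (`EA`) and last (`LA`) `window` strides of a
#' series. The window is 3 strides for the SLA statistics, 5 for peak
#' activations, and 20 for the kinematics comparison.
#'
#' @param y numeric series.
#' @param window window length in strides.
#' @return list(ea, la, window).
#' @export
windows <- function(y, window = 3L) {
  window <- as.integer(window)
  if (window < 1 || window > length(y))
    stop("windows: window exceeds series length")
  list(ea = mean(y[seq_len(window)]),
       la = mean(y[seq(length(y) - window + 1L, length(y))]),
       window = window)
}
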