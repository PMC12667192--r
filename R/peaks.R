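# Peak muscle activations per stride, with light smoothing to suppress
# single-sample spikes.

#' Peak muscle activations over strides
#'
#' For each stride (delimited by consecutive heel strikes of the chosen
#' leg) and each muscle, the maximum activation after a moving-average
#' smoothing window (default 10 ms). Used for early/late adaptation
#' comparisons (first and last five strides).
#'
#' @param traj a recorded trajectory from [simulate_gait()].
#' @param leg which leg's heel strikes delimit strides ("fast"/"slow").
#' @param smooth_s smoothing window in seconds (default 0.010).
#' @return matrix strides x muscles of peak activations.
#' @export
peak_activations <- function(traj, leg = "fast", smooth_s = 0.010) {
  stopifnot(!is.null(traj$act), !is.null(traj$time))
  hs <- traj$events$time[traj$events$leg == leg & traj$events$type == "HS"]
  if (length(hs) < 3) stop("peak_activations: too few heel strikes")
  dt <- stats::median(diff(traj$time))
  k <- max(1L, round(smooth_s / dt))
  kern <- rep(1 / k, k)
  sm <- apply(traj$act, 2, function(a)
    stats::filter(a, kern, sides = 2))
  sm[is.na(sm)] <- traj$act[is.na(sm)]
  out <- t(vapply(seq_len(length(hs) - 1L), function(s) {
    idx <- which(traj$time >= hs[s] & traj$time < hs[s + 1L])
    apply(sm[idx, , drop = FALSE], 2, max)
  }, numeric(ncol(traj$act))))
  colnames(out) <- c(paste0(MUSCLE_NAMES, "_l"), paste0(MUSCLE_NAMES, "_r"))
  out
}
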