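#' Wrist range-of-motion features
#'
#' The wrist angle is the cumulative trapezoidal integral of angular
#' velocity, linearly detrended to control gyroscope drift (no orientation
#' filter is assumed). The trend line is anchored at the first and last
#' samples: a least-squares line would absorb part of the oscillation itself
#' and inflate the range, whereas the endpoint line removes a constant rate
#' bias exactly. ROM is the peak-to-peak detrended angle; cycle count comes
#' from zero crossings of the detrended angle.
#'
#' @param omega_dps angular velocity samples in degrees/second.
#' @param rate_hz sampling rate.
#' @return list: `wrt_rom_deg`, `wrt_cycles`, `wrt_mean_absvel`.
#' @export
extract_wrt_features <- function(omega_dps, rate_hz) {
  if (!all(is.finite(omega_dps))) stopf("angular-velocity stream has non-finite samples")
  if (length(omega_dps) / rate_hz < 5) stopf("recording shorter than 5 s")
  t <- (seq_along(omega_dps) - 1) / rate_hz
  ang <- pracma::cumtrapz(t, omega_dps)[, 1]
  n <- length(ang)
  slope <- (ang[n] - ang[1]) / (t[n] - t[1])
  ang <- ang - ang[1] - slope * t
  cross <- sum(diff(sign(ang[ang != 0])) != 0)
  list(wrt_rom_deg = max(ang) - min(ang),
       wrt_cycles = cross / 2,
       wrt_mean_absvel = mean(abs(omega_dps)))
}

#' Walking-test features
#'
#' The acceleration magnitude is band-passed to the locomotion band
#' (0.5-3 Hz); steps are peaks above an adaptive threshold (0.3 x the
#' band-passed sd) separated by at least 0.25 s, so the count is invariant
#' to global magnitude scaling. Step regularity is the autocorrelation of
#' the band-passed magnitude at the dominant period.
#'
#' @param xyz `n x 3` acceleration matrix (g) of the nominally 30-s walk.
#' @param rate_hz sampling rate.
#' @return list: `wlk_steps`, `wlk_cadence` (steps/min), `wlk_regularity`,
#'   `wlk_short_flag` (1 when the recording is shorter than 28 s).
#' @export
extract_wlk_features <- function(xyz, rate_hz) {
  m <- sqrt(rowSums(xyz^2))
  dur <- length(m) / rate_hz
  short <- dur < 28
  if (short) warning("walking recording shorter than expected (", round(dur, 1), " s)")
  bf <- signal::butter(2, c(0.5, 3) / (rate_hz / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, m - mean(m)))
  s <- stats::sd(bp)
  if (s < 1e-8) {
    return(list(wlk_steps = 0, wlk_cadence = 0, wlk_regularity = NA_real_,
                wlk_short_flag = as.numeric(short)))
  }
  pk <- pracma::findpeaks(bp, minpeakheight = 0.3 * s,
                          minpeakdistance = max(1L, as.integer(0.25 * rate_hz)))
  steps <- if (is.null(pk)) 0 else nrow(pk)
  # dominant period from the periodogram
  sp <- stats::spec.pgram(bp, plot = FALSE, taper = 0, detrend = FALSE)
  f_dom <- sp$freq[which.max(sp$spec)] * rate_hz
  reg <- NA_real_
  if (f_dom > 0) {
    lag <- as.integer(round(rate_hz / f_dom))
    if (lag >= 1 && lag < length(bp)) {
      ac <- stats::acf(bp, lag.max = lag, plot = FALSE)$acf
      reg <- ac[lag + 1]
    }
  }
  list(wlk_steps = steps, wlk_cadence = steps / dur * 60,
       wlk_regularity = reg, wlk_short_flag = as.numeric(short))
}

#' Nine-hole peg test features
#'
#' @param events strictly increasing touch-event times in seconds.
#' @return list: `peg_completion_s`, `peg_mean_interval`, `peg_sd_interval`
#'   (`NA` with fewer than 3 events).
#' @export
extract_peg_features <- function(events) {
  if (length(events) < 2) stopf("need at least 2 touch events")
  if (any(diff(events) <= 0)) stopf("touch events must be strictly increasing")
  iv <- diff(events)
  list(peg_completion_s = events[length(events)] - events[1],
       peg_mean_interval = mean(iv),
       peg_sd_interval = if (length(iv) >= 2) stats::sd(iv) else NA_real_)
}

#' Postural transition features
#'
#' Detects the single sit-to-stand or lie-to-stand transition between two
#' quasi-static orientation plateaus. The vertical axis is taken as the axis
#' with the largest plateau-level change of its low-passed component;
#' plateau levels are medians of the first and last second. The transition
#' interval is the 10-90% crossing of the low-passed vertical component,
#' rescaled by 1/0.8 so that a linear ramp of duration `d` yields duration
#' `d`. Smoothness is the negative log of the mean squared jerk of the
#' magnitude during the transition.
#'
#' @param xyz `n x 3` acceleration matrix containing one transition.
#' @param rate_hz sampling rate.
#' @param prefix feature-name prefix, `"sts"` or `"lts"`.
#' @return list: `<prefix>_duration_s`, `<prefix>_peak_mag`,
#'   `<prefix>_smoothness`, `<prefix>_detect_fail` (1 when no plateau
#'   structure was found).
#' @export
extract_transition_features <- function(xyz, rate_hz, prefix = "sts") {
  nm <- function(s) paste0(prefix, "_", s)
  fail <- stats::setNames(
    list(NA_real_, NA_real_, NA_real_, 1),
    c(nm("duration_s"), nm("peak_mag"), nm("smoothness"), nm("detect_fail")))
  n <- nrow(xyz)
  w <- min(n, as.integer(rate_hz))       # 1-s plateau windows
  bf <- signal::butter(2, min(0.99, 2 / (rate_hz / 2)), type = "low")
  lp <- apply(xyz, 2, function(col) as.numeric(signal::filtfilt(bf, col)))
  lev1 <- apply(lp[seq_len(w), , drop = FALSE], 2, stats::median)
  lev2 <- apply(lp[(n - w + 1):n, , drop = FALSE], 2, stats::median)
  ax <- which.max(abs(lev2 - lev1))
  a1 <- lev1[ax]; a2 <- lev2[ax]
  if (abs(a2 - a1) < 0.1) return(fail)   # no orientation change
  v <- lp[, ax]
  frac <- (v - a1) / (a2 - a1)
  i90 <- which(frac >= 0.9)[1]
  if (is.na(i90)) return(fail)
  before <- which(frac[seq_len(i90)] <= 0.1)
  if (!length(before)) return(fail)
  i10 <- before[length(before)]
  dur <- (i90 - i10) / rate_hz / 0.8
  m <- sqrt(rowSums(xyz^2))
  seg <- m[i10:i90]
  jerk <- diff(seg) * rate_hz
  smooth <- if (length(jerk)) -log(mean(jerk^2) + 1e-12) else NA_real_
  stats::setNames(list(dur, max(seg), smooth, 0),
                  c(nm("duration_s"), nm("peak_mag"), nm("smoothness"),
                    nm("detect_fail")))
}

#' All guided-test features for one participant
#'
#' @param gt a [simulate_guided_tests()] recording set.
#' @return long data.frame (`participant_id`, `day_index`, `feature`,
#'   `domain`, `value`) with one block per day.
#' @export
active_daily_features <- function(gt) {
  rows <- lapply(seq_along(gt$days), function(d) {
    rec <- gt$days[[d]]
    feats <- c(
      extract_wrt_features(rec$wrt$omega_dps, rec$wrt$rate_hz),
      extract_wlk_features(rec$wlk$xyz, rec$wlk$rate_hz),
      extract_peg_features(rec$peg),
      extract_transition_features(rec$sts$xyz, rec$sts$rate_hz, "sts"),
      extract_transition_features(rec$lts$xyz, rec$lts$rate_hz, "lts"))
    summarize_daily(gt$participant_id, d, feats)
  })
  do.call(rbind, rows)
}
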