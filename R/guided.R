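#' Simulate guided smartphone test recordings
#'
#' Generates one recording per test per day for a participant: a wrist
#' range-of-motion (ROM) angular-velocity stream whose integrated angle has
#' the participant's peak-to-peak ROM, a 30-s walking acceleration stream at
#' the participant's step cadence, ordered touch-event times for a digital
#' 9-hole peg test, and sit-to-stand / lie-to-stand acceleration streams
#' containing a single postural transition of the participant's duration.
#' Day-to-day variation is added around each participant's latent values, so
#' the recordings carry both group effects and within-person noise.
#'
#' @param p one-row participant record.
#' @param n_days number of study days.
#' @param cfg an [effect_config()].
#' @return object of class `guided_tests`: list of per-day lists with
#'   elements `wrt` (list: `rate_hz`, `omega_dps`), `wlk` (list: `rate_hz`,
#'   `xyz`), `peg` (numeric event times, s), `sts`, `lts` (lists: `rate_hz`,
#'   `xyz`, each with one transition).
#' @export
simulate_guided_tests <- function(p, n_days, cfg = effect_config()) {
  if (n_days < 1) stopf("n_days must be >= 1")
  g <- cfg$guided; sym <- cfg$symptoms
  set.seed(derive_seed(cfg$seed, "guided", p$participant_id))
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    # wrist ROM: omega(t) = (R/2) * 2*pi*f * cos(2*pi*f*t)  [deg/s]
    rom <- max(10, stats::rnorm(1, p$lat_rom_deg, sym$rom_day_sd_deg))
    t_w <- seq(0, g$wrt_dur_s, by = 1 / g$wrt_rate_hz)
    omega <- (rom / 2) * 2 * pi * g$wrt_freq_hz *
      cos(2 * pi * g$wrt_freq_hz * t_w) +
      stats::rnorm(length(t_w), 0, g$wrt_noise_dps)

    # 30-s walk: vertical oscillation at the step frequency
    cad <- max(0.6, stats::rnorm(1, p$lat_cadence_hz, sym$cadence_day_sd_hz))
    t_k <- seq(0, g$wlk_dur_s, by = 1 / g$wlk_rate_hz)
    amp <- g$step_amp_g * stats::runif(1, 0.9, 1.1)
    z <- 1 + amp * sin(2 * pi * cad * t_k) +
      stats::rnorm(length(t_k), 0, g$wlk_noise_g)
    wlk <- cbind(stats::rnorm(length(t_k), 0, g$wlk_noise_g),
                 stats::rnorm(length(t_k), 0, g$wlk_noise_g), z)

    # 9-hole peg test: strictly increasing touch events
    iv <- pmax(0.3, stats::rnorm(g$peg_n_events - 1, p$lat_peg_s, sym$peg_jitter_s))
    peg <- cumsum(c(stats::runif(1, 0.5, 1.5), iv))

    sts <- transition_stream(max(0.4, stats::rnorm(1, p$lat_transition_s,
                                                   sym$transition_day_sd_s)),
                             lo = 0.50, hi = 0.95, g)
    lts <- transition_stream(max(0.5, g$lts_factor *
                                   stats::rnorm(1, p$lat_transition_s,
                                                sym$transition_day_sd_s)),
                             lo = 0.05, hi = 0.95, g)
    days[[d]] <- list(
      wrt = list(rate_hz = g$wrt_rate_hz, omega_dps = omega),
      wlk = list(rate_hz = g$wlk_rate_hz, xyz = wlk),
      peg = peg, sts = sts, lts = lts)
  }
  structure(list(participant_id = p$participant_id, days = days),
            class = "guided_tests")
}

# one postural transition: linear ramp of the low-passed vertical axis
# between two orientation plateaus, plus a movement burst during the ramp
transition_stream <- function(dur_s, lo, hi, g) {
  fs <- g$trans_rate_hz
  t <- seq(0, g$trans_dur_s, by = 1 / fs)
  t0 <- (g$trans_dur_s - dur_s) / 2
  frac <- pmin(1, pmax(0, (t - t0) / dur_s))
  z <- lo + (hi - lo) * frac
  burst <- 0.15 * (frac > 0 & frac < 1)
  x <- sqrt(pmax(0, 1 - z^2))
  xyz <- cbind(x + stats::rnorm(length(t), 0, g$trans_noise_g) +
                 burst * stats::rnorm(length(t)),
               stats::rnorm(length(t), 0, g$trans_noise_g),
               z + stats::rnorm(length(t), 0, g$trans_noise_g))
  list(rate_hz = fs, xyz = xyz, true_duration_s = dur_s)
}

#' @export
print.guided_tests <- function(x, ...) {
  cat(sprintf("Guided-test recordings: %s, %d days (WRT, WLK, PEG, STS, LTS)\n",
              x$participant_id, length(x$days)))
  invisible(x)
}
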