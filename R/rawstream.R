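#' Synthesise a raw tri-axial wrist acceleration stream
#'
#' Sample-level generative model for the smartwatch accelerometer, driven by
#' a true activity sequence. Each sample is a slowly rotating gravity unit
#' vector (class-specific orientation-drift rate) plus a zero-mean dynamic
#' component whose standard deviation increases sleep < sedentary < light <
#' MVPA. The same symptom effects as [epoch_magnitudes()] are applied: the
#' dynamic component in the post-wake window is attenuated by the morning
#' factor and night-time movement episodes are injected during sleep.
#'
#' @param seq an [simulate_activity_days()] result.
#' @param p the matching participant record (a one-row [generate_cohort()]
#'   slice); pass `NULL` for a symptom-free stream.
#' @param cfg an [effect_config()]; `cfg$sample_rate_hz` sets the rate.
#' @return an object of class `tri_stream`: list with `participant_id`,
#'   `sample_rate_hz`, `start_s` and an `n x 3` matrix `xyz` in g.
#' @export
synthesize_raw_stream <- function(seq, p = NULL, cfg = effect_config()) {
  fs <- cfg$sample_rate_hz
  epl <- seq$epoch_len_s
  spe <- as.integer(fs * epl)          # samples per epoch
  lab <- as.character(seq$labels)
  n_ep <- length(lab)
  n <- n_ep * spe
  pid <- seq$participant_id %||% "P000"
  set.seed(derive_seed(cfg$seed, "raw", pid))

  sd_ep <- cfg$noise$dynamic_sd[lab]
  rot_ep <- cfg$noise$gravity_rot_rate[lab]

  # symptom modulation at epoch resolution
  if (!is.null(p)) {
    sl <- detect_sleep_periods(seq, gap_merge_min = 30)
    mf <- p$lat_morning_factor %||% 1
    if (nrow(sl) && mf < 1) {
      win_ep <- as.integer(cfg$symptoms$morning_window_min * 60 / epl)
      for (i in seq_len(nrow(sl))) {
        a <- as.integer(sl$offset_s[i] / epl) + 1L
        b <- min(n_ep, a + win_ep - 1L)
        if (a <= n_ep) sd_ep[a:b] <- sd_ep[a:b] * mf
      }
    }
    rate <- p$lat_night_rate %||% 0
    if (nrow(sl) && rate > 0) {
      for (i in seq_len(nrow(sl))) {
        a <- max(1L, as.integer(sl$onset_s[i] / epl) + 1L)
        b <- min(n_ep, as.integer(sl$offset_s[i] / epl))
        if (b <= a) next
        k <- stats::rpois(1, rate * (b - a + 1) * epl / 3600)
        if (k == 0) next
        starts <- sample(a:b, k, replace = TRUE)
        lens <- stats::rgeom(k, 1 / cfg$symptoms$episode_len_epochs) + 1L
        for (j in seq_len(k)) {
          idx <- starts[j]:min(b, starts[j] + lens[j] - 1L)
          sd_ep[idx] <- pmax(sd_ep[idx], cfg$symptoms$episode_amp_g)
        }
      }
    }
  }

  # slowly rotating gravity direction: random walk on two angles
  dtheta <- stats::rnorm(n_ep, 0, rot_ep)
  dphi <- stats::rnorm(n_ep, 0, rot_ep)
  theta <- cumsum(rep(dtheta / spe, each = spe)) + pi / 4
  phi <- cumsum(rep(dphi / spe, each = spe))
  grav <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

  sdv <- rep(sd_ep, each = spe)
  dyn <- matrix(stats::rnorm(3 * n, 0, 1), ncol = 3) * sdv
  structure(list(participant_id = pid, sample_rate_hz = fs,
                 start_s = seq$epoch_start_s[1] %||% 0,
                 xyz = grav + dyn),
            class = "tri_stream")
}

#' @export
print.tri_stream <- function(x, ...) {
  cat(sprintf("Tri-axial stream: %s, %d samples at %g Hz (%.1f min)\n",
              x$participant_id, nrow(x$xyz), x$sample_rate_hz,
              nrow(x$xyz) / x$sample_rate_hz / 60))
  invisible(x)
}

stream_magnitude <- function(stream) sqrt(rowSums(stream$xyz^2))
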