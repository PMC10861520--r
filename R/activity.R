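#' Simulate a participant's true activity label sequence
#'
#' Generates a semi-Markov sequence of 30-s epoch labels over the broad
#' activity taxonomy for `n_days` days. Each night has one main sleep block
#' (onset near the configured clock hour, allowed to span midnight); daytime
#' epochs are filled by a semi-Markov process whose class weights are derived
#' from the participant's whole-day activity fractions and whose dwell times
#' are geometric with the configured means. The participant's latent
#' multipliers scale light and MVPA time, so RA participants spend less time
#' in moderate-to-vigorous activity in expectation.
#'
#' @param p a single-row participant record from [generate_cohort()].
#' @param n_days number of study days (>= 1).
#' @param cfg an [effect_config()].
#' @return an object of class `activity_seq`: list with `participant_id`,
#'   `epoch_len_s`, `epoch_start_s`, `labels` (factor over the taxonomy) and
#'   `n_days`.
#' @export
simulate_activity_days <- function(p, n_days, cfg = effect_config()) {
  if (n_days < 1) stopf("n_days must be >= 1")
  classes <- activity_classes(cfg$taxonomy)
  if (cfg$taxonomy != "broad")
    stopf("the generator only emits the broad taxonomy")
  act <- cfg$activity
  epl <- cfg$epoch_len_s
  epd <- as.integer(86400 / epl)
  n_ep <- n_days * epd

  set.seed(derive_seed(cfg$seed, "activity", p$participant_id))

  g <- as.character(p$group)
  fr <- act$fractions[g, ]
  # participant-level adjustment: scale light/MVPA, sedentary absorbs
  fr["MVPA"] <- fr["MVPA"] * (p$lat_mvpa_mult %||% 1)
  fr["light"] <- fr["light"] * (p$lat_light_mult %||% 1)
  fr["sedentary"] <- 1 - fr["sleep"] - fr["light"] - fr["MVPA"]
  if (fr["sedentary"] < 0) { fr[c("light", "MVPA")] <- fr[c("light", "MVPA")] *
      (1 - fr["sleep"]) / sum(fr[c("light", "MVPA")]); fr["sedentary"] <- 0 }

  lab <- integer(n_ep)   # 0 = unfilled; otherwise index into classes

  # nightly main sleep blocks; night k wakes on day k (k = 0 .. n_days-1),
  # plus a final night starting on the last day
  sleep_h <- fr[["sleep"]] * 24
  for (k in 0:n_days) {
    onset_s <- (k - 1) * 86400 +
      stats::rnorm(1, act$sleep_onset_h, act$sleep_onset_sd_h) * 3600
    dur_s <- max(0, stats::rnorm(1, sleep_h, act$sleep_dur_sd_h) * 3600)
    a <- max(0, floor(onset_s / epl))
    b <- min(n_ep, ceiling((onset_s + dur_s) / epl))
    if (b > a) lab[(a + 1):b] <- 1L   # class 1 = sleep
  }

  # fill remaining epochs with the daytime semi-Markov process
  open <- which(lab == 0L)
  if (length(open)) {
    day_classes <- c("sedentary", "light", "MVPA")
    fday <- fr[day_classes]
    if (sum(fday) <= 0) {
      lab[open] <- 2L   # degenerate: all sedentary
    } else {
      fday <- fday / sum(fday)
      dw <- act$dwell_epochs[day_classes]
      q <- fday / dw
      q <- q / sum(q)
      # draw enough runs to cover the open epochs
      need <- length(open)
      est_runs <- ceiling(need / sum(q * dw) * 1.5) + 20
      cls <- sample.int(3L, est_runs, replace = TRUE, prob = q)
      len <- stats::rgeom(est_runs, prob = 1 / dw[cls]) + 1L
      while (sum(len) < need) {
        cls2 <- sample.int(3L, 50L, replace = TRUE, prob = q)
        len2 <- stats::rgeom(50L, prob = 1 / dw[cls2]) + 1L
        cls <- c(cls, cls2); len <- c(len, len2)
      }
      filler <- rep.int(cls, len)[seq_len(need)] + 1L  # offset: sedentary = 2
      lab[open] <- filler
    }
  }

  structure(list(
    participant_id = p$participant_id,
    epoch_len_s = epl,
    epoch_start_s = (seq_len(n_ep) - 1) * epl,
    labels = factor(classes[lab], levels = classes),
    n_days = n_days
  ), class = "activity_seq")
}

#' @export
print.activity_seq <- function(x, ...) {
  cat(sprintf("Activity sequence: %s, %d days, %d epochs of %gs\n",
              x$participant_id, x$n_days, length(x$labels), x$epoch_len_s))
  print(round(prop.table(table(x$labels)), 3))
  invisible(x)
}

#' Per-epoch movement magnitudes consistent with an activity sequence
#'
#' Draws, for every epoch, the mean acceleration magnitude (in g) implied by
#' the package's raw-signal generative model without synthesising the
#' sample-level signal: magnitude is 1 g (gravity) plus a class-dependent
#' dynamic component. RA symptom effects are applied on top: movement in the
#' configured post-wake window is attenuated by the participant's morning
#' factor, and night-time movement episodes are injected into sleep at the
#' participant's Poisson rate.
#'
#' @param seq an [simulate_activity_days()] result.
#' @param p the matching participant record.
#' @param cfg an [effect_config()].
#' @return numeric vector of per-epoch magnitudes, aligned with `seq$labels`.
#' @export
epoch_magnitudes <- function(seq, p, cfg = effect_config()) {
  set.seed(derive_seed(cfg$seed, "mags", p$participant_id))
  lab <- as.character(seq$labels)
  n <- length(lab)
  sdv <- cfg$noise$dynamic_sd[lab]
  # epoch means concentrate around the class level; between-epoch variation
  # is multiplicative with ~10% coefficient of variation
  mags <- 1 + sdv * exp(0.1 * stats::rnorm(n))

  sym <- cfg$symptoms
  epl <- seq$epoch_len_s
  sl <- detect_sleep_periods(seq, gap_merge_min = 30)

  # morning attenuation: first `morning_window_min` minutes after each wake
  mf <- p$lat_morning_factor %||% 1
  if (nrow(sl) && mf < 1) {
    win_ep <- as.integer(sym$morning_window_min * 60 / epl)
    for (i in seq_len(nrow(sl))) {
      a <- as.integer(sl$offset_s[i] / epl) + 1L
      b <- min(n, a + win_ep - 1L)
      if (a <= n) mags[a:b] <- 1 + mf * (mags[a:b] - 1)
    }
  }

  # night-time movement episodes within main sleep windows
  rate <- p$lat_night_rate %||% 0
  if (nrow(sl) && rate > 0) {
    for (i in seq_len(nrow(sl))) {
      a <- max(1L, as.integer(sl$onset_s[i] / epl) + 1L)
      b <- min(n, as.integer(sl$offset_s[i] / epl))
      if (b <= a) next
      dur_h <- (b - a + 1) * epl / 3600
      k <- stats::rpois(1, rate * dur_h)
      if (k == 0) next
      starts <- sample(a:b, k, replace = TRUE)
      lens <- stats::rgeom(k, 1 / sym$episode_len_epochs) + 1L
      for (j in seq_len(k)) {
        idx <- starts[j]:min(b, starts[j] + lens[j] - 1L)
        mags[idx] <- 1 + sym$episode_amp_g *
          (1 + 0.2 * abs(stats::rnorm(length(idx))))
      }
    }
  }
  mags
}
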