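#' Activity taxonomies
#'
#' The two labelling conventions used throughout the package. The broad
#' taxonomy is `{sleep, sedentary, light, MVPA}`; the fine-grained taxonomy is
#' `{sleep, sitting/standing, mixed, vehicle, walking, bicycling}`.
#'
#' @param name `"broad"` or `"fine"`.
#' @return character vector of ordered class labels.
#' @export
activity_classes <- function(name = c("broad", "fine")) {
  name <- match.arg(name)
  switch(name,
    broad = c("sleep", "sedentary", "light", "MVPA"),
    fine  = c("sleep", "sitting/standing", "mixed", "vehicle", "walking",
              "bicycling"))
}

#' Effect configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic cohort: per-group
#' patient-reported-outcome (PRO) distributions, activity composition,
#' RA symptom effects (morning movement attenuation, night-time movement
#' episodes, slowed postural transitions, reduced wrist range of motion),
#' sensor noise scales, and the master seed. Groups are always ordered
#' `HC`, `RA_mod`, `RA_sev`.
#'
#' Default PRO and demographic distributions follow the baseline summary of
#' a 14-day remote-monitoring RA study (28-30 healthy controls, 13 moderate
#' and 15 severe RA participants): healthy controls have degenerate HAQ-DI
#' and RAPID-3 at zero, RA groups show graded disability, pain and fatigue.
#' Activity composition encodes the lower moderate-to-vigorous physical
#' activity (MVPA) observed in RA.
#'
#' @param seed integer master seed; identical configurations produce
#'   bit-identical synthetic data.
#' @param ... named overrides for any default component (replaced wholesale).
#' @return an object of class `effect_config`.
#' @export
effect_config <- function(seed = 1L, ...) {
  grp <- function(hc, mod, sev) c(HC = hc, RA_mod = mod, RA_sev = sev)
  cfg <- list(
    seed = as.integer(seed),
    epoch_len_s = 30,
    sample_rate_hz = 30,
    taxonomy = "broad",

    # PRO instruments: per-group mean/sd (truncated normal) and score range
    pro = list(
      haq_di          = list(mean = grp(0, 0.63, 1.03), sd = grp(0, 0.36, 0.42),
                             range = c(0, 3)),
      rasiq_pain      = list(mean = grp(3.1, 32.1, 56.2), sd = grp(6.7, 20.8, 11.6),
                             range = c(0, 100)),
      rasiq_stiffness = list(mean = grp(5.9, 33.9, 51.6), sd = grp(9.5, 18.9, 10.2),
                             range = c(0, 100)),
      rasiq_impact    = list(mean = grp(47.3, 53.9, 50.8), sd = grp(5.0, 5.1, 7.6),
                             range = c(0, 100)),
      facit           = list(mean = grp(49.2, 38.9, 31.9), sd = grp(2.9, 4.3, 7.6),
                             range = c(0, 52)),
      promis_sleep    = list(mean = grp(49.6, 52.7, 52.4), sd = grp(2.8, 4.2, 4.3),
                             range = c(20, 80)),
      promis_pain     = list(mean = grp(42.2, 54.2, 58.8), sd = grp(4.8, 7.29, 4.6),
                             range = c(20, 80))
    ),
    # in-clinic composite severity score, 0-10 scale; HC fixed at zero
    rapid3 = list(mean = grp(0, 3.2, 5.3), sd = grp(0, 0.7, 1.1),
                  range = c(0, 10)),

    demographics = list(
      age = list(mean = grp(58.4, 56.9, 60.4), sd = grp(9.9, 11.4, 7.1),
                 range = c(18, 90)),
      bmi = list(mean = grp(25.8, 31.1, 31.7), sd = grp(4.6, 5.9, 8.6),
                 range = c(15, 60)),
      female_prob = grp(0.89, 0.84, 0.93)
    ),

    # whole-day activity fractions per group (rows sum to 1)
    activity = list(
      fractions = rbind(
        HC     = c(sleep = 0.33, sedentary = 0.45, light = 0.17, MVPA = 0.05),
        RA_mod = c(sleep = 0.34, sedentary = 0.50, light = 0.13, MVPA = 0.03),
        RA_sev = c(sleep = 0.35, sedentary = 0.53, light = 0.10, MVPA = 0.02)),
      # mean dwell (epochs) of daytime semi-Markov runs
      dwell_epochs = c(sedentary = 20, light = 6, MVPA = 4),
      sleep_onset_h = 23.0,      # clock hour of sleep onset
      sleep_onset_sd_h = 0.5,
      sleep_dur_sd_h = 0.5,
      # between-subject multiplicative variation of light/MVPA time
      mvpa_rel_sd = 0.15,
      light_rel_sd = 0.10
    ),

    # symptom effects; per-group means with between-subject / day-to-day sds
    symptoms = list(
      morning_factor = grp(1.0, 0.70, 0.50),  # multiplier on dynamic movement
      morning_factor_sd = 0.05,               # in first 30 min after wake
      morning_window_min = 30,
      night_rate_per_h = grp(0.5, 1.2, 2.0),  # movement episodes during sleep
      night_rate_rel_sd = 0.20,
      episode_amp_g = 0.10,                   # magnitude bump of an episode
      episode_len_epochs = 2,                 # mean geometric episode length
      transition_s = grp(1.5, 2.2, 3.0),      # sit-to-stand duration
      transition_sd_s = 0.25, transition_day_sd_s = 0.15,
      rom_deg = grp(140, 110, 90),            # wrist range of motion
      rom_sd_deg = 8, rom_day_sd_deg = 3,
      cadence_hz = grp(1.9, 1.7, 1.5),        # walking step frequency
      cadence_sd_hz = 0.07, cadence_day_sd_hz = 0.03,
      peg_interval_s = grp(1.5, 2.2, 3.0),    # 9-hole peg inter-event mean
      peg_sd_s = 0.20, peg_jitter_s = 0.30
    ),

    # raw tri-axial accelerometer generative model (units of g)
    noise = list(
      dynamic_sd = c(sleep = 0.005, sedentary = 0.01, light = 0.05, MVPA = 0.15),
      gravity_rot_rate = c(sleep = 0.001, sedentary = 0.005, light = 0.02,
                           MVPA = 0.05)   # rad per sample-step of drift
    ),

    guided = list(
      wrt_dur_s = 10, wrt_freq_hz = 0.25, wrt_rate_hz = 50, wrt_noise_dps = 2,
      wlk_dur_s = 30, wlk_rate_hz = 50, step_amp_g = 0.35, wlk_noise_g = 0.02,
      peg_n_events = 9,
      trans_rate_hz = 50, trans_dur_s = 8, trans_noise_g = 0.01,
      lts_factor = 1.3   # lie-to-stand transitions take longer than sit-to-stand
    ),

    dropout_prob = 0   # per participant-day probability of missing wear
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "effect_config"
  validate_effect_config(cfg)
  cfg
}

validate_effect_config <- function(cfg) {
  fr <- cfg$activity$fractions
  if (any(abs(rowSums(fr) - 1) > 1e-8))
    stopf("activity fractions must sum to 1 per group")
  if (any(fr < 0)) stopf("activity fractions must be nonnegative")
  for (nm in names(cfg$pro)) {
    if (any(cfg$pro[[nm]]$sd < 0))
      stopf("PRO '%s' has negative dispersion", nm)
  }
  if (any(cfg$rapid3$sd < 0)) stopf("rapid3 dispersion must be nonnegative")
  if (any(cfg$activity$dwell_epochs <= 0)) stopf("dwell means must be positive")
  if (!cfg$taxonomy %in% c("broad", "fine")) stopf("unknown taxonomy '%s'", cfg$taxonomy)
  invisible(cfg)
}

#' @export
print.effect_config <- function(x, ...) {
  cat("Synthetic study effect configuration\n")
  cat("  seed:", x$seed, " taxonomy:", x$taxonomy,
      " epoch:", x$epoch_len_s, "s\n")
  cat("  PRO instruments:", paste(names(x$pro), collapse = ", "), "\n")
  cat("  MVPA fraction (HC/RA_mod/RA_sev):",
      paste(x$activity$fractions[, "MVPA"], collapse = "/"), "\n")
  invisible(x)
}
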