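#' Detect main sleep periods
#'
#' Nights are defined noon-to-noon (the window centred on each midnight), so
#' a sleep block spanning midnight is never split. Within each night, sleep
#' runs separated by gaps of at most `gap_merge_min` minutes are merged
#' (brief awakenings should not split the main sleep), and the longest
#' merged run is the night's main sleep. The wake-up time used by the
#' morning-stiffness features is the offset of the main sleep.
#'
#' @param seq an `activity_seq` whose taxonomy contains a `sleep` class.
#' @param gap_merge_min merge sleep runs separated by gaps up to this many
#'   minutes.
#' @return data.frame with `night_index` (0-based; night `k` is centred on
#'   the midnight starting day `k+1`), `onset_s`, `offset_s`, `duration_h`.
#'   Nights with no sleep epochs are absent.
#' @export
detect_sleep_periods <- function(seq, gap_merge_min = 30) {
  if (!"sleep" %in% levels(seq$labels)) stopf("taxonomy has no sleep class")
  epl <- seq$epoch_len_s
  is_sleep <- seq$labels == "sleep"
  n <- length(is_sleep)
  gap_ep <- as.integer(gap_merge_min * 60 / epl)
  out <- list()
  for (k in 0:(seq$n_days - 1)) {
    lo_s <- k * 86400 - 43200
    hi_s <- k * 86400 + 43200
    a <- max(1L, as.integer(lo_s / epl) + 1L)
    b <- min(n, as.integer(hi_s / epl))
    if (b < a) next
    r <- runs_of(is_sleep[a:b])
    r <- r[r$value, , drop = FALSE]
    if (!nrow(r)) next
    # merge runs with short gaps
    merged <- r[1, c("start", "end")]
    if (nrow(r) > 1) for (i in 2:nrow(r)) {
      if (r$start[i] - merged$end[nrow(merged)] - 1L <= gap_ep) {
        merged$end[nrow(merged)] <- r$end[i]
      } else {
        merged <- rbind(merged, r[i, c("start", "end")])
      }
    }
    merged$len <- merged$end - merged$start + 1L
    main <- merged[which.max(merged$len), ]
    onset <- (a - 1L + main$start - 1L) * epl
    offset <- (a - 1L + main$end) * epl
    out[[length(out) + 1]] <- data.frame(
      night_index = k, onset_s = onset, offset_s = offset,
      duration_h = (offset - onset) / 3600)
  }
  if (!length(out))
    return(data.frame(night_index = integer(0), onset_s = numeric(0),
                      offset_s = numeric(0), duration_h = numeric(0)))
  do.call(rbind, out)
}

#' Total volume of daytime activity (TVDA) features for one day
#'
#' Fraction of the day in each activity class, minutes of MVPA, and the mean
#' and 95th percentile of daytime movement magnitude, daytime meaning epochs
#' outside the main sleep windows.
#'
#' @param seq an `activity_seq`.
#' @param mags per-epoch movement magnitudes aligned with `seq` (gravity
#'   removed).
#' @param day 1-based day index.
#' @param sleep optional precomputed [detect_sleep_periods()] result.
#' @return named list of features (empty if the day is absent).
#' @export
compute_tvda_features <- function(seq, mags, day, sleep = NULL) {
  epl <- seq$epoch_len_s
  idx <- which(seq$epoch_start_s >= (day - 1) * 86400 &
               seq$epoch_start_s < day * 86400)
  if (!length(idx)) return(list())
  if (is.null(sleep)) sleep <- detect_sleep_periods(seq)
  in_sleep <- rep(FALSE, length(seq$labels))
  for (i in seq_len(nrow(sleep))) {
    a <- as.integer(sleep$onset_s[i] / epl) + 1L
    b <- as.integer(sleep$offset_s[i] / epl)
    in_sleep[max(1L, a):min(length(in_sleep), b)] <- TRUE
  }
  fr <- prop.table(table(seq$labels[idx]))
  out <- as.list(stats::setNames(as.numeric(fr),
                                 paste0("tvda_frac_", names(fr))))
  out$tvda_mvpa_min <- sum(seq$labels[idx] == "MVPA") * epl / 60
  dayt <- idx[!in_sleep[idx]]
  if (length(dayt)) {
    out$tvda_day_mag_mean <- mean(mags[dayt])
    out$tvda_day_mag_p95 <- unname(stats::quantile(mags[dayt], 0.95))
  } else {
    out$tvda_day_mag_mean <- NA_real_
    out$tvda_day_mag_p95 <- NA_real_
  }
  out
}

#' Morning movement (stiffness surrogate) features
#'
#' Mean movement magnitude in the first 30 minutes after wake-up (early
#' window), in the following hour (post window), and their ratio. A ratio
#' below 1 indicates attenuated movement right after waking, the behavioural
#' signature of RA morning stiffness.
#'
#' @param mags per-epoch movement magnitudes.
#' @param wake_s wake-up time in seconds since study start.
#' @param epoch_len_s epoch length of `mags`.
#' @return list with `morn_early_mag`, `morn_post_mag`, `morn_ratio`;
#'   all `NA` when fewer than 90 minutes of data follow the wake time.
#' @export
compute_morning_stiffness <- function(mags, wake_s, epoch_len_s = 30) {
  a <- as.integer(wake_s / epoch_len_s) + 1L
  b30 <- a + as.integer(30 * 60 / epoch_len_s) - 1L
  b90 <- a + as.integer(90 * 60 / epoch_len_s) - 1L
  if (b90 > length(mags) || a < 1)
    return(list(morn_early_mag = NA_real_, morn_post_mag = NA_real_,
                morn_ratio = NA_real_))
  early <- mean(mags[a:b30])
  post <- mean(mags[(b30 + 1):b90])
  list(morn_early_mag = early, morn_post_mag = post,
       morn_ratio = if (post > 0) early / post else NA_real_)
}

#' Night-time restlessness features
#'
#' A movement episode is a maximal run of sleep epochs whose magnitude
#' exceeds a threshold; the default threshold is the mean night magnitude
#' plus three standard deviations of the quiet reference (the below-median
#' half of the night's epochs).
#'
#' @param mags per-epoch movement magnitudes.
#' @param window one row of [detect_sleep_periods()] output.
#' @param epoch_len_s epoch length of `mags`.
#' @param threshold optional explicit threshold overriding the default.
#' @return list with `ntr_episodes`, `ntr_minutes`, `ntr_per_hour`; all `NA`
#'   for windows shorter than one hour.
#' @export
compute_night_restlessness <- function(mags, window, epoch_len_s = 30,
                                       threshold = NULL) {
  a <- max(1L, as.integer(window$onset_s / epoch_len_s) + 1L)
  b <- min(length(mags), as.integer(window$offset_s / epoch_len_s))
  if (b < a || (b - a + 1) * epoch_len_s < 3600)
    return(list(ntr_episodes = NA_real_, ntr_minutes = NA_real_,
                ntr_per_hour = NA_real_))
  m <- mags[a:b]
  if (is.null(threshold)) {
    quiet <- m[m <= stats::median(m)]
    threshold <- mean(m) + 3 * stats::sd(quiet)
    if (!is.finite(threshold)) threshold <- mean(m)
  }
  above <- m > threshold
  r <- runs_of(above)
  eps <- r[r$value, , drop = FALSE]
  dur_h <- (b - a + 1) * epoch_len_s / 3600
  list(ntr_episodes = nrow(eps),
       ntr_minutes = sum(eps$length) * epoch_len_s / 60,
       ntr_per_hour = nrow(eps) / dur_h)
}

#' Activity fragmentation (AF) features for one day
#'
#' Epochs are dichotomised to active (light + MVPA in the broad taxonomy;
#' walking / bicycling / mixed in the fine taxonomy) versus rest. Features:
#' the active-to-rest transition probability (transitions divided by active
#' epochs), the mean active bout length in minutes, and the bout count.
#'
#' @inheritParams compute_tvda_features
#' @return named list of features.
#' @export
compute_activity_fragmentation <- function(seq, day) {
  idx <- which(seq$epoch_start_s >= (day - 1) * 86400 &
               seq$epoch_start_s < day * 86400)
  if (!length(idx)) return(list())
  active_classes <- if ("MVPA" %in% levels(seq$labels))
    c("light", "MVPA") else c("walking", "bicycling", "mixed")
  act <- seq$labels[idx] %in% active_classes
  n_active <- sum(act)
  trans <- sum(act[-length(act)] & !act[-1])
  r <- runs_of(act)
  bouts <- r[r$value, , drop = FALSE]
  list(
    af_trans_prob = if (n_active > 0) trans / n_active else NA_real_,
    af_mean_bout_min = if (nrow(bouts)) mean(bouts$length) *
      seq$epoch_len_s / 60 else NA_real_,
    af_bout_count = nrow(bouts))
}

# feature name -> domain registry used for group tags
feature_domain <- function(feature) {
  pre <- c(tvda = "TVDA", sleep = "SLEEP", morn = "MORN", ntr = "NTR",
           af = "AF", wrt = "WRT", wlk = "WLK", peg = "PEG", sts = "STS",
           lts = "LTS", dem = "DEM", pro = "PRO")
  key <- sub("_.*$", "", feature)
  out <- unname(pre[key])
  out[is.na(out)] <- "OTHER"
  out
}

#' Assemble one participant-day feature row
#'
#' Combines passive and active feature maps with replicated demographic
#' (DEM) features into a tidy long block; every feature is tagged with its
#' domain. Missing features propagate as `NA`, never as zero.
#'
#' @param participant_id,day_index identifiers for the row.
#' @param ... named lists of features (as produced by the `compute_*` and
#'   `extract_*` functions).
#' @param demographics optional named list/vector of demographic features
#'   (emitted with a `dem_` prefix).
#' @return data.frame with columns `participant_id`, `day_index`, `feature`,
#'   `domain`, `value`.
#' @export
summarize_daily <- function(participant_id, day_index, ...,
                            demographics = NULL) {
  feats <- unlist(list(...), recursive = FALSE)
  if (!is.null(demographics)) {
    names(demographics) <- paste0("dem_", sub("^dem_", "", names(demographics)))
    feats <- c(feats, as.list(demographics))
  }
  if (!length(feats)) stopf("no features supplied")
  vals <- vapply(feats, function(v) as.numeric(v[1]), numeric(1))
  data.frame(participant_id = participant_id, day_index = day_index,
             feature = names(vals), domain = feature_domain(names(vals)),
             value = unname(vals), stringsAsFactors = FALSE, row.names = NULL)
}

#' All passive features for one participant
#'
#' Runs sleep detection and the TVDA / MORN / NTR / AF feature extractors
#' over every study day and returns the tidy long table.
#'
#' @param seq an `activity_seq`.
#' @param mags per-epoch movement magnitudes (gravity removed).
#' @param record optional one-row cohort record supplying DEM features.
#' @return long data.frame as in [summarize_daily()], plus per-night sleep
#'   features (duration, onset hour) attached to the wake day.
#' @export
passive_daily_features <- function(seq, mags, record = NULL) {
  sleep <- detect_sleep_periods(seq)
  dem <- if (!is.null(record))
    list(age = record$age, sex = as.numeric(record$sex == "F"),
         bmi = record$bmi) else NULL
  rows <- list()
  for (day in seq_len(seq$n_days)) {
    night <- sleep[sleep$night_index == day - 1, , drop = FALSE]
    tvda <- compute_tvda_features(seq, mags, day, sleep = sleep)
    af <- compute_activity_fragmentation(seq, day)
    if (nrow(night)) {
      w <- night[1, ]
      slp <- list(sleep_duration_h = w$duration_h,
                  sleep_onset_h = ((w$onset_s / 3600) %% 24))
      morn <- compute_morning_stiffness(mags, w$offset_s, seq$epoch_len_s)
      ntr <- compute_night_restlessness(mags, w, seq$epoch_len_s)
    } else {
      slp <- list(sleep_duration_h = NA_real_, sleep_onset_h = NA_real_)
      morn <- list(morn_early_mag = NA_real_, morn_post_mag = NA_real_,
                   morn_ratio = NA_real_)
      ntr <- list(ntr_episodes = NA_real_, ntr_minutes = NA_real_,
                  ntr_per_hour = NA_real_)
    }
    rows[[day]] <- summarize_daily(seq$participant_id, day,
                                   tvda, slp, morn, ntr, af,
                                   demographics = dem)
  }
  do.call(rbind, rows)
}
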