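make_neutral_participant <- function(cfg, group = "HC") {
  co <- generate_cohort(1, 0, 0, cfg)
  co$group <- factor(group, levels = c("HC", "RA_mod", "RA_sev"))
  co$lat_mvpa_mult <- 1; co$lat_light_mult <- 1
  co
}

test_that("a simulated day has exactly 2880 epochs of 30 s", {
  cfg <- effect_config(seed = 9)
  p <- generate_cohort(1, 0, 0, cfg)[1, ]
  sq <- simulate_activity_days(p, 14, cfg)
  expect_length(sq$labels, 14 * 2880)
  expect_equal(sq$epoch_start_s[2] - sq$epoch_start_s[1], 30)
})

test_that("empirical class fractions track the configured composition", {
  cfg <- effect_config(seed = 31)
  cfg$activity$mvpa_rel_sd <- 0; cfg$activity$light_rel_sd <- 0
  p_hc <- make_neutral_participant(cfg, "HC")
  p_sev <- make_neutral_participant(cfg, "RA_sev")
  fr_of <- function(p) {
    sq <- simulate_activity_days(p, 14, cfg)
    mean(sq$labels == "MVPA")
  }
  expect_lt(abs(fr_of(p_hc) - 0.05), 0.01)
  expect_lt(abs(fr_of(p_sev) - 0.02), 0.01)
})

test_that("all mass on sedentary yields a constant daytime sequence", {
  cfg <- effect_config(seed = 12)
  cfg$activity$fractions["HC", ] <- c(sleep = 0, sedentary = 1, light = 0,
                                      MVPA = 0)
  p <- make_neutral_participant(cfg)
  sq <- simulate_activity_days(p, 1, cfg)
  expect_true(all(sq$labels[sq$labels != "sleep"] == "sedentary"))
})

test_that("the generator is seed-deterministic end to end", {
  cfg <- effect_config(seed = 55)
  p <- generate_cohort(1, 0, 0, cfg)[1, ]
  a <- simulate_activity_days(p, 2, cfg)
  b <- simulate_activity_days(p, 2, cfg)
  expect_identical(a, b)
  expect_identical(epoch_magnitudes(a, p, cfg), epoch_magnitudes(b, p, cfg))
})

test_that("MVPA ordering HC > RA_mod > RA_sev holds empirically", {
  cfg <- effect_config(seed = 404)
  co <- generate_cohort(30, 30, 30, cfg)
  mv <- vapply(seq_len(nrow(co)), function(i) {
    mean(simulate_activity_days(co[i, ], 14, cfg)$labels == "MVPA")
  }, numeric(1))
  m <- tapply(mv, co$group, mean)
  expect_gt(m[["HC"]], m[["RA_mod"]])
  expect_gt(m[["RA_mod"]], m[["RA_sev"]])
})

test_that("sleep-only raw stream magnitude stays within 3% of 1 g", {
  cfg <- effect_config(seed = 8)
  sq <- make_seq(rep("sleep", 2 * 120), n_days = 1)  # 2 h of sleep
  st <- synthesize_raw_stream(sq, p = NULL, cfg = cfg)
  m <- sqrt(rowSums(st$xyz^2))
  expect_gte(mean(m >= 0.97 & m <= 1.03), 0.99)
})

test_that("dynamic variance ordering sleep < sedentary < light < MVPA", {
  cfg <- effect_config(seed = 8)
  vs <- vapply(c("sleep", "sedentary", "light", "MVPA"), function(cl) {
    sq <- make_seq(rep(cl, 60), n_days = 1)
    st <- synthesize_raw_stream(sq, p = NULL, cfg = cfg)
    stats::var(sqrt(rowSums(st$xyz^2)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("night-episode injection matches its Poisson rate", {
  cfg <- effect_config(seed = 66)
  # one 8-h night of sleep inside a 24-h day
  labels <- rep("sedentary", 2880)
  labels[1:960] <- "sleep"
  sq <- make_seq(labels, n_days = 1)
  counts <- vapply(1:200, function(r) {
    cfg_r <- cfg; cfg_r$seed <- 1000 + r
    p <- generate_cohort(1, 0, 0, cfg_r)[1, ]
    p$lat_night_rate <- 2; p$lat_morning_factor <- 1
    mags <- pmax(epoch_magnitudes(sq, p, cfg_r) - 1, 0)
    w <- detect_sleep_periods(sq)[1, ]
    compute_night_restlessness(mags, w, 30)$ntr_episodes
  }, numeric(1))
  expect_lt(abs(mean(counts) - 16), 2)
})

test_that("morning attenuation lowers the post-wake movement ratio in RA", {
  cfg <- effect_config(seed = 123)
  co <- generate_cohort(30, 0, 30, cfg)
  ratio <- vapply(seq_len(nrow(co)), function(i) {
    p <- co[i, ]
    sq <- simulate_activity_days(p, 3, cfg)
    mags <- pmax(epoch_magnitudes(sq, p, cfg) - 1, 0)
    sl <- detect_sleep_periods(sq)
    mean(vapply(seq_len(nrow(sl)), function(k)
      compute_morning_stiffness(mags, sl$offset_s[k], 30)$morn_ratio,
      numeric(1)), na.rm = TRUE)
  }, numeric(1))
  hc <- ratio[co$group == "HC"]; sev <- ratio[co$group == "RA_sev"]
  expect_gt(mean(hc, na.rm = TRUE), mean(sev, na.rm = TRUE))
  expect_lt(mann_whitney_u(hc[!is.na(hc)], sev[!is.na(sev)])$p_value, 0.01)
})
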