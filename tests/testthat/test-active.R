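test_that("wrist ROM recovers the closed-form sinusoid amplitude", {
  rate <- 50
  t <- seq(0, 10, by = 1 / rate)
  omega <- 45 * pi * cos(pi * t)         # angle = 45 sin(pi t), ROM 90
  f <- extract_wrt_features(omega, rate)
  expect_lt(abs(f$wrt_rom_deg - 90), 2)
  expect_equal(extract_wrt_features(rep(0, 500), rate)$wrt_rom_deg, 0)
  # linearity: doubling the velocity doubles the ROM
  f2 <- extract_wrt_features(2 * omega, rate)
  expect_equal(f2$wrt_rom_deg / f$wrt_rom_deg, 2, tolerance = 1e-6)
  # constant gyro bias is removed by the detrend
  f3 <- extract_wrt_features(omega + 3, rate)
  expect_lt(abs(f3$wrt_rom_deg - f$wrt_rom_deg), 1)
})

test_that("walking features count steps of a known oscillation", {
  rate <- 50
  t <- seq(0, 30, by = 1 / rate)
  xyz <- cbind(0, 0, 1 + 0.3 * sin(2 * pi * 2 * t))
  f <- extract_wlk_features(xyz, rate)
  expect_equal(f$wlk_steps, 60, tolerance = 0.05)
  expect_equal(f$wlk_cadence, 120, tolerance = 3)
  expect_gt(f$wlk_regularity, 0.9)
  z <- extract_wlk_features(cbind(0, 0, rep(1, length(t))), rate)
  expect_equal(z$wlk_steps, 0)
  expect_true(is.na(z$wlk_regularity))
  # adaptive threshold: global scaling leaves the count unchanged
  f4 <- extract_wlk_features(4 * xyz, rate)
  expect_equal(f4$wlk_steps, f$wlk_steps)
})

test_that("peg-test features are simple event arithmetic", {
  f <- extract_peg_features(seq(0, 16, by = 2))
  expect_equal(f$peg_completion_s, 16)
  expect_equal(f$peg_mean_interval, 2)
  expect_equal(f$peg_sd_interval, 0)
  two <- extract_peg_features(c(1, 3))
  expect_equal(two$peg_completion_s, 2)
  expect_true(is.na(two$peg_sd_interval))
  expect_error(extract_peg_features(c(1, 1, 2)), "increasing")
  set.seed(31)
  sds <- vapply(1:200, function(r) {
    extract_peg_features(cumsum(pmax(0.3, rnorm(9, 2, 0.3))))$peg_sd_interval
  }, numeric(1))
  expect_gt(mean(sds), 0.2)
  expect_lt(mean(sds), 0.4)
})

test_that("transition duration matches the generating ramp", {
  rate <- 50
  t <- seq(0, 8, by = 1 / rate)
  ramp <- function(dur) {
    frac <- pmin(1, pmax(0, (t - (8 - dur) / 2) / dur))
    z <- 0.5 + 0.45 * frac
    cbind(sqrt(pmax(0, 1 - z^2)), 0, z)
  }
  f <- extract_transition_features(ramp(2), rate, "sts")
  expect_lt(abs(f$sts_duration_s - 2), 0.1)
  expect_equal(f$sts_detect_fail, 0)
  # near-instantaneous step: duration bounded by the low-pass response,
  # far below any physiological transition
  f2 <- extract_transition_features(ramp(0.04), rate, "sts")
  expect_lt(f2$sts_duration_s, 0.5)
  expect_lt(f2$sts_duration_s, f$sts_duration_s / 3)
  # no orientation change: detection failure flagged
  flat <- cbind(0.1, 0, matrix(0.9, length(t)))
  f3 <- extract_transition_features(flat, rate, "sts")
  expect_equal(f3$sts_detect_fail, 1)
  expect_true(is.na(f3$sts_duration_s))
})

test_that("guided-test recordings separate RA from HC transitions", {
  cfg <- effect_config(seed = 91)
  co <- generate_cohort(30, 0, 30, cfg)
  dur <- vapply(seq_len(nrow(co)), function(i) {
    gt <- simulate_guided_tests(co[i, ], 1, cfg)
    active_daily_features(gt)$value[
      active_daily_features(gt)$feature == "sts_duration_s"][1]
  }, numeric(1))
  hc <- dur[co$group == "HC"]; sev <- dur[co$group == "RA_sev"]
  expect_lt(mann_whitney_u(hc, sev)$p_value, 0.01)
  expect_lt(stats::median(hc), stats::median(sev))
})

test_that("generator round-trip recovers configured ROM and peg pace", {
  cfg <- effect_config(seed = 14)
  p <- generate_cohort(1, 0, 0, cfg)[1, ]
  gt <- simulate_guided_tests(p, 8, cfg)
  af <- active_daily_features(gt)
  rom <- af$value[af$feature == "wrt_rom_deg"]
  expect_lt(abs(mean(rom) - p$lat_rom_deg), 5)
  peg <- af$value[af$feature == "peg_mean_interval"]
  expect_lt(abs(mean(peg) - p$lat_peg_s), 0.4)
})
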