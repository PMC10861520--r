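test_that("main sleep detection picks the longest merged run per night", {
  # night 0 window is [-12 h, +12 h); build an 8-h run starting at 23:00
  # of the previous day is not representable, so use the run after midnight
  lab <- rep("sedentary", 2880)
  lab[1:(8 * 120)] <- "sleep"                 # 00:00-08:00
  sl <- detect_sleep_periods(make_seq(lab, n_days = 1))
  expect_equal(nrow(sl), 1)
  expect_equal(sl$duration_h, 8)

  # two runs, 6 h and 1 h, separated by 2 h: the 6-h run wins
  lab2 <- rep("sedentary", 2880)
  lab2[1:(6 * 120)] <- "sleep"
  lab2[(8 * 120 + 1):(9 * 120)] <- "sleep"
  sl2 <- detect_sleep_periods(make_seq(lab2, n_days = 1))
  expect_equal(sl2$duration_h, 6)

  # 4-h run + 20-min gap + 3-h run merge into one 7h20 window
  lab3 <- rep("sedentary", 2880)
  lab3[1:(4 * 120)] <- "sleep"
  lab3[(4 * 120 + 41):(4 * 120 + 40 + 3 * 120)] <- "sleep"
  sl3 <- detect_sleep_periods(make_seq(lab3, n_days = 1))
  expect_equal(sl3$duration_h, 4 + 20 / 60 + 3, tolerance = 1e-9)
})

test_that("TVDA features follow the stated arithmetic", {
  lab <- rep("sedentary", 2880)
  lab[100 + seq_len(48)] <- "MVPA"
  sq <- make_seq(lab, n_days = 1)
  f <- compute_tvda_features(sq, rep(0.02, 2880), 1)
  expect_equal(f$tvda_mvpa_min, 24)
  fr <- unlist(f[grep("^tvda_frac", names(f))])
  expect_equal(sum(fr), 1)

  allsed <- compute_tvda_features(make_seq(rep("sedentary", 2880), n_days = 1),
                                  rep(0.02, 2880), 1)
  expect_equal(allsed$tvda_frac_sedentary, 1)
  expect_false("tvda_frac_MVPA" %in% names(allsed) &&
                 isTRUE(allsed$tvda_frac_MVPA > 0))
  expect_equal(compute_tvda_features(sq, rep(0.02, 2880), 5), list())
})

test_that("morning ratio is early/post with a 90-min data requirement", {
  mags <- c(rep(0.02, 60), rep(0.04, 120), rep(0.03, 120))
  f <- compute_morning_stiffness(mags, wake_s = 0, epoch_len_s = 30)
  expect_equal(f$morn_early_mag, 0.02)
  expect_equal(f$morn_post_mag, 0.04)
  expect_equal(f$morn_ratio, 0.5)
  f2 <- compute_morning_stiffness(rep(0.05, 180), 0, 30)
  expect_equal(f2$morn_ratio, 1)
  # under 90 min of post-wake data: all features null
  f3 <- compute_morning_stiffness(rep(0.05, 100), 0, 30)
  expect_true(is.na(f3$morn_ratio))
})

test_that("night restlessness counts threshold-exceeding runs", {
  w <- data.frame(night_index = 0, onset_s = 0, offset_s = 8 * 3600,
                  duration_h = 8)
  mags <- rep(0.005, 960)
  starts <- c(50, 200, 400, 600, 800)
  for (s in starts) mags[s:(s + 2)] <- 0.1
  f <- compute_night_restlessness(mags, w, 30)
  expect_equal(f$ntr_episodes, 5)
  expect_equal(f$ntr_minutes, 5 * 3 * 30 / 60)
  quiet <- compute_night_restlessness(rep(0.005, 960), w, 30)
  expect_equal(quiet$ntr_episodes, 0)
  short <- compute_night_restlessness(mags, data.frame(
    night_index = 0, onset_s = 0, offset_s = 1800, duration_h = 0.5), 30)
  expect_true(is.na(short$ntr_episodes))
})

test_that("fragmentation features match hand counts", {
  lab <- c("light", "light", "sedentary", "MVPA", "sedentary")
  sq <- make_seq(c(lab, rep("sedentary", 2875)), n_days = 1)
  f <- compute_activity_fragmentation(sq, 1)
  expect_equal(f$af_trans_prob, 2 / 3)
  expect_equal(f$af_bout_count, 2)

  allact <- compute_activity_fragmentation(
    make_seq(rep("light", 2880), n_days = 1), 1)
  expect_equal(allact$af_trans_prob, 0)

  alt <- compute_activity_fragmentation(
    make_seq(rep(c("light", "sedentary"), 1440), n_days = 1), 1)
  expect_equal(alt$af_trans_prob, 1)
})

test_that("daily summary rows carry domains and propagate missingness", {
  row <- summarize_daily("P001", 3,
                         list(tvda_mvpa_min = 10, morn_ratio = NA_real_),
                         demographics = list(age = 60, sex = 1, bmi = 24))
  expect_equal(nrow(row), 5)
  expect_true(is.na(row$value[row$feature == "morn_ratio"]))
  expect_setequal(row$domain[row$feature %in% c("dem_age", "dem_sex",
                                                "dem_bmi")], "DEM")
  expect_false(any(row$domain == "OTHER"))
})

test_that("group differences in passive features survive FDR control", {
  st <- fixture_study()
  groups <- fixture_groups()
  pass <- st$daily[st$daily$domain %in% c("TVDA", "MORN", "NTR", "AF",
                                          "SLEEP"), ]
  rep <- univariate_report(pass, ifelse(groups == "HC", "HC", "RA"),
                           comparison = "hc_vs_ra")
  mv <- rep[rep$feature == "tvda_frac_MVPA", ]
  mo <- rep[rep$feature == "morn_ratio", ]
  expect_true(mv$significant)
  expect_true(mo$significant)
  # most passive features separate the groups under these effect sizes
  expect_gt(mean(rep$significant, na.rm = TRUE), 0.5)
})
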