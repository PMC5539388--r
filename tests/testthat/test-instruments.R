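test_that("daily minutes bin into the 8 diary categories", {
  expect_equal(bin_ema_minutes(24), 3)   # 20-29 min bin
  expect_equal(bin_ema_minutes(0), 1)
  expect_equal(bin_ema_minutes(200), 8)  # top-coded
  expect_equal(bin_ema_minutes(c(9, 10, 69, 70, 70.5)), c(1, 2, 7, 8, 8))
  expect_error(bin_ema_minutes(-1), "non-negative")
  expect_error(bin_ema_minutes(Inf), "finite")
})

test_that("category scoring returns the in-bin mean", {
  expect_equal(score_ema_category(3), 24.5)
  expect_equal(score_ema_category(1), 4.5)
  expect_equal(score_ema_category(8), 70)  # open-ended top category
  expect_equal(score_ema_category(8, ema_midpoints(top_value = 85)), 85)
  expect_error(score_ema_category(0), "1..8")
  expect_error(score_ema_category(9), "1..8")
})

test_that("diary weeks sum answered days without rescaling", {
  r <- data.frame(participant_id = "a", day_index = 1:7,
                  moderate_category = 3, vigorous_category = 1)
  w <- score_ema_week(r)
  expect_equal(w$moderate_min_wk, 171.5)  # 7 x 24.5
  expect_equal(w$vigorous_min_wk, 31.5)   # 7 x 4.5
  expect_equal(w$mvpa_min_wk, 203)

  # single answered day, both intensities top-coded: no rescaling
  r1 <- data.frame(participant_id = "a", day_index = 4,
                   moderate_category = 8, vigorous_category = 8)
  expect_equal(score_ema_week(r1)$mvpa_min_wk, 140)
  expect_equal(score_ema_week(r1, rescale_to_7_days = TRUE)$mvpa_min_wk,
               140 * 7)

  # no answered days: missing estimate
  r0 <- data.frame(participant_id = "a", day_index = 1:3,
                   moderate_category = NA, vigorous_category = NA)
  w0 <- score_ema_week(r0)
  expect_true(is.na(w0$moderate_min_wk) && is.na(w0$mvpa_min_wk))
  expect_equal(w0$n_days_used, 0)

  dup <- rbind(r1, r1)
  expect_error(score_ema_week(dup), "duplicate")
  expect_error(score_ema_week(transform(r1, day_index = 9)), "1..7")
})

test_that("duration x frequency items score as weekly products", {
  r <- data.frame(participant_id = c("a", "b", "c"),
                  moderate_min_per_day = c(30, 0, NA),
                  moderate_times_per_week = c(5, 0, 4),
                  vigorous_min_per_day = c(20, 0, 20),
                  vigorous_times_per_week = c(3, 0, 3))
  w <- score_brfss(r)
  expect_equal(w$moderate_min_wk[1], 150)
  expect_equal(w$vigorous_min_wk[1], 60)
  expect_equal(w$mvpa_min_wk[1], 210)
  expect_equal(unlist(w[2, c("moderate_min_wk", "vigorous_min_wk",
                             "mvpa_min_wk")], use.names = FALSE),
               c(0, 0, 0))
  # missing moderate propagates to moderate and MVPA but not vigorous
  expect_true(is.na(w$moderate_min_wk[3]) && is.na(w$mvpa_min_wk[3]))
  expect_equal(w$vigorous_min_wk[3], 60)
  expect_error(score_brfss(transform(r, moderate_min_per_day = -5)),
               "non-negative")
})

test_that("occupational/transport items score days x hours x 60", {
  base <- data.frame(participant_id = "a",
                     occ_vigorous_days = 0, occ_vigorous_hours = 0,
                     occ_moderate_days = 0, occ_moderate_hours = 0,
                     occ_walk_days = 0, occ_walk_hours = 0,
                     transport_walk_days = 0, transport_walk_hours = 0,
                     transport_bike_days = 0, transport_bike_hours = 0,
                     sit_weekday_h = 0, sit_weekend_h = 0)
  r <- transform(base, occ_vigorous_days = 2, occ_vigorous_hours = 1)
  w <- score_ipaq(r)
  expect_equal(w$vigorous_min_wk, 120)
  expect_equal(w$moderate_min_wk, 0)
  expect_equal(w$mvpa_min_wk, 120)

  # transport bicycling counts as moderate
  r <- transform(base, transport_bike_days = 5, transport_bike_hours = 0.5)
  expect_equal(score_ipaq(r)$moderate_min_wk, 150)

  w0 <- score_ipaq(base)
  expect_equal(unlist(w0[c("sedentary_min_wk", "moderate_min_wk",
                           "vigorous_min_wk", "mvpa_min_wk")],
                      use.names = FALSE), c(0, 0, 0, 0))

  # sitting: (5 x weekday + 2 x weekend) x 60
  r <- transform(base, sit_weekday_h = 8, sit_weekend_h = 6)
  expect_equal(score_ipaq(r)$sedentary_min_wk, (5 * 8 + 2 * 6) * 60)

  expect_error(score_ipaq(transform(base, occ_walk_days = 8)), "0..7")
})

test_that("screen-time items score with the 5/2 day weighting", {
  r <- data.frame(participant_id = "a", tv_weekday_h = 2, tv_weekend_h = 4,
                  computer_weekday_h = 1, computer_weekend_h = 1)
  expect_equal(score_screen_time(r)$sedentary_min_wk, 1500)
  r0 <- transform(r, tv_weekday_h = 0, tv_weekend_h = 0,
                  computer_weekday_h = 0, computer_weekend_h = 0)
  expect_equal(score_screen_time(r0)$sedentary_min_wk, 0)
  # impossible combined report: error by default, cap on request
  r24 <- data.frame(participant_id = "a", tv_weekday_h = 24,
                    tv_weekend_h = 24, computer_weekday_h = 24,
                    computer_weekend_h = 24)
  expect_error(score_screen_time(r24), "24 h/day")
  expect_equal(score_screen_time(r24, cap_at_week = TRUE)$sedentary_min_wk,
               10080)
  expect_error(score_screen_time(transform(r, tv_weekday_h = 25)),
               "\\[0, 24\\]")
})

test_that("scored estimates are non-negative, additive and bounded", {
  set.seed(55)
  co <- generate_cohort(cohort_params(n_participants = 30, seed = 7))
  est <- score_instruments(co$ema, co$brfss, co$ipaq, co$screen)
  expect_true(all(est$minutes_wk >= 0, na.rm = TRUE))
  wide <- split(est, est$instrument)
  for (inst in c("ema", "brfss", "ipaq")) {
    w <- wide[[inst]]
    m <- w$minutes_wk[w$intensity == "moderate"]
    v <- w$minutes_wk[w$intensity == "vigorous"]
    mv <- w$minutes_wk[w$intensity == "mvpa"]
    both <- !is.na(m) & !is.na(v)
    expect_equal(mv[both], (m + v)[both])
  }
  # diary weekly estimates bounded by 7 x top-category midpoint
  ema <- wide$ema
  expect_true(all(ema$minutes_wk[ema$intensity != "mvpa"] <= 7 * 70,
                  na.rm = TRUE))
})
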