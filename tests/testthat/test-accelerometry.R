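test_that("degenerate days classify correctly", {
  expect_equal(sum(detect_nonwear(rep(0L, 1440))), 0)       # all nonwear
  expect_equal(sum(detect_nonwear(rep(500L, 1440))), 1440)  # no zero run
})

test_that("allowance epochs are absorbed into a nonwear window", {
  day <- c(rep(0L, 90), rep(50L, 2), rep(0L, 90), rep(500L, 1440 - 182))
  worn <- detect_nonwear(day)
  expect_equal(which(!worn), 1:182)  # one 182-minute window
  expect_equal(sum(worn), 1440 - 182)
  expect_equal(worn, oracle_nonwear_scan(day))
})

test_that("interruptions beyond the allowance terminate the window", {
  pad <- function(zeros1, mid, zeros2) {
    c(rep(0L, zeros1), mid, rep(0L, zeros2),
      rep(500L, 1440 - zeros1 - length(mid) - zeros2))
  }
  # three consecutive nonzero epochs split the zero run: each half < 60
  day <- pad(50, rep(50L, 3), 50)
  expect_equal(sum(!detect_nonwear(day)), 0)
  # a single epoch above 100 cpm splits it too
  day <- pad(50, 101L, 50)
  expect_equal(sum(!detect_nonwear(day)), 0)
  # two epochs at exactly 100 cpm are absorbed
  day <- pad(50, rep(100L, 2), 50)
  expect_equal(sum(!detect_nonwear(day)), 102)
  # halves long enough stand alone even when the interruption fails
  day <- pad(70, rep(50L, 3), 70)
  expect_equal(sum(!detect_nonwear(day)), 140)
})

test_that("trailing interruptions are not absorbed", {
  # zeros, then allowance-band epochs, then activity: the window must
  # end on the last zero
  day <- c(rep(0L, 80), rep(50L, 2), rep(500L, 1440 - 82))
  expect_equal(which(!detect_nonwear(day)), 1:80)
})

test_that("run-length implementation agrees with both independent oracles", {
  set.seed(401)
  for (rep in 1:40) {
    day <- random_epoch_day(1440)
    expect_equal(detect_nonwear(day), oracle_nonwear_scan(day))
  }
  # exhaustive window enumeration at small n, including short-run edge
  # cases around the 60-minute threshold
  for (rep in 1:25) {
    n <- sample(60:150, 1)
    day <- random_epoch_day(n)
    expect_equal(detect_nonwear(day), oracle_nonwear_windows(day))
  }
})

test_that("adding counts to an epoch never increases nonwear time", {
  set.seed(402)
  for (rep in 1:25) {
    day <- random_epoch_day(1440)
    nw_before <- !detect_nonwear(day)
    i <- sample.int(1440, 1)
    day2 <- day
    day2[i] <- day2[i] + sample(c(1L, 60L, 500L), 1)
    nw_after <- !detect_nonwear(day2)
    expect_true(all(which(nw_after) %in% which(nw_before)))
  }
})

test_that("epochs are classified into exactly one intensity band", {
  day <- rep(50L, 1440)
  s <- classify_epochs(day, detect_nonwear(day))
  expect_equal(s$sedentary_min, 1440)
  expect_equal(s$wear_min, 1440)
  expect_true(s$valid)

  day <- c(rep(c(2000L, 6000L), 300), rep(0L, 840))
  s <- classify_epochs(day, detect_nonwear(day))
  expect_equal(s$wear_min, 600)
  expect_equal(s$moderate_min, 300)
  expect_equal(s$vigorous_min, 300)
  expect_true(s$valid)

  # all-nonwear day: zero in every category, invalid
  s <- classify_epochs(rep(0L, 1440), detect_nonwear(rep(0L, 1440)))
  expect_equal(unlist(s[c("wear_min", "sedentary_min", "light_min",
                          "moderate_min", "vigorous_min")]),
               c(wear_min = 0, sedentary_min = 0, light_min = 0,
                 moderate_min = 0, vigorous_min = 0))
  expect_false(s$valid)

  expect_error(classify_epochs(rep(1L, 1440), rep(TRUE, 10)), "mask")
})

test_that("intensity minutes always partition wear time", {
  set.seed(403)
  for (rep in 1:20) {
    day <- random_epoch_day(1440)
    s <- daily_summary(day)
    expect_equal(s$sedentary_min + s$light_min + s$moderate_min +
                   s$vigorous_min, s$wear_min)
  }
})

test_that("weekly estimates follow the valid-day rule", {
  mk <- function(mods, valid = TRUE) {
    data.frame(wear_min = 700, sedentary_min = 700 - mods, light_min = 0,
               moderate_min = mods, vigorous_min = 0, valid = valid)
  }
  # 3 valid days out of 7: excluded
  d <- rbind(mk(10), mk(10), mk(10), mk(10, FALSE), mk(10, FALSE),
             mk(10, FALSE), mk(10, FALSE))
  expect_true(is.na(weekly_accel_estimate(d)$moderate_min_wk))
  expect_equal(weekly_accel_estimate(d)$n_days_used, 3)
  # 7 constant valid days
  d <- do.call(rbind, replicate(7, mk(20), simplify = FALSE))
  expect_equal(weekly_accel_estimate(d)$moderate_min_wk, 140)
  # day-mean x 7 scaling
  d <- rbind(mk(10), mk(20), mk(30), mk(40))
  w <- weekly_accel_estimate(d)
  expect_equal(w$moderate_min_wk, 25 * 7)
  expect_equal(w$mvpa_min_wk, w$moderate_min_wk + w$vigorous_min_wk)
  # alternative scaling: plain sum over valid days
  expect_equal(weekly_accel_estimate(d, scale = "sum_valid")$moderate_min_wk,
               100)
})

test_that("epoch CSV round trip preserves weekly estimates", {
  co <- generate_cohort(cohort_params(n_participants = 3, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  epochs <- read_epoch_csv(file.path(dir, "epochs.csv"))
  from_csv <- process_epochs(epochs)
  from_mat <- process_epochs(list(counts = co$counts, key = co$key))
  expect_equal(from_csv$weekly, from_mat$weekly)
})

test_that("timestamp,counts exports are parsed into epoch days", {
  ts <- seq(as.POSIXct("2012-05-01 00:00", tz = "UTC"),
            by = "1 min", length.out = 2880)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "P9.csv")
  utils::write.csv(data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                              counts = rep(100L, 2880)),
                   path, row.names = FALSE)
  df <- read_epoch_csv(path)
  expect_equal(unique(df$participant_id), "P9")
  expect_equal(sort(unique(df$day)), 1:2)
  expect_equal(range(df$minute), c(0, 1439))
  daily <- process_epochs(df)$daily
  expect_equal(daily$wear_min, c(1440, 1440))
})
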