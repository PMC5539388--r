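#' EMA response-category midpoints
#'
#' The daily diary offers 8 duration options in 10-minute increments
#' (0-9, 10-19, ..., 60-69, >= 70 minutes). Scoring uses the mean value
#' within each category: a response of 20-29 minutes scores 24.5
#' minutes. The open-ended top category has no interior mean and scores
#' its lower bound (70 by default, configurable).
#'
#' @param top_value Minutes credited to the open-ended top category.
#' @return Numeric vector of 8 midpoints.
#' @export
#' @examples
#' ema_midpoints()[3]  # 24.5
ema_midpoints <- function(top_value = 70) {
  stopifnot(is.numeric(top_value), top_value >= 70)
  c(seq(4.5, 64.5, by = 10), top_value)
}

#' Bin reported daily minutes into an EMA response category
#'
#' @param minutes Non-negative finite minutes.
#' @return Integer category 1..8 for bins 0-9, 10-19, ..., 60-69, >= 70.
#' @export
#' @examples
#' bin_ema_minutes(24)  # 3
bin_ema_minutes <- function(minutes) {
  if (!is.numeric(minutes) || anyNA(minutes) || any(!is.finite(minutes))) {
    stop("minutes must be finite and non-missing")
  }
  if (any(minutes < 0)) stop("minutes must be non-negative")
  as.integer(pmin(floor(minutes / 10), 7) + 1L)
}

#' Score one EMA response category as minutes
#'
#' @param category Integer category 1..8.
#' @param midpoints Category midpoint table, see [ema_midpoints()].
#' @return Minutes credited to the category.
#' @export
score_ema_category <- function(category, midpoints = ema_midpoints()) {
  stopifnot(length(midpoints) == 8)
  if (anyNA(category) || any(category < 1 | category > 8) ||
      any(category != floor(category))) {
    stop("category must be an integer in 1..8")
  }
  midpoints[category]
}

#' Score a week of EMA daily-diary responses
#'
#' Category responses are converted to minutes via the midpoint table
#' and summed across all answered days; missing days are neither imputed
#' nor rescaled unless `rescale_to_7_days = TRUE` (off by default:
#' answered-day sums are the instrument's weekly estimate). A
#' participant with no answered days gets a missing estimate.
#'
#' @param responses Data frame with columns `participant_id`,
#'   `day_index` (1..7), `moderate_category`, `vigorous_category`
#'   (1..8 or `NA`).
#' @param midpoints Category midpoint table.
#' @param rescale_to_7_days If `TRUE`, scale each intensity sum by
#'   7 / answered days for that intensity.
#' @return Per-participant data frame with `moderate_min_wk`,
#'   `vigorous_min_wk`, `mvpa_min_wk`, `n_days_used`,
#'   `instrument = "ema"`.
#' @export
score_ema_week <- function(responses, midpoints = ema_midpoints(),
                           rescale_to_7_days = FALSE) {
  need <- c("participant_id", "day_index", "moderate_category",
            "vigorous_category")
  stopifnot(all(need %in% names(responses)))
  if (any(responses$day_index < 1 | responses$day_index > 7)) {
    stop("day_index must lie in 1..7")
  }
  out <- lapply(split(responses, responses$participant_id), function(r) {
    if (anyDuplicated(r$day_index)) {
      stop("duplicate day_index for participant ", r$participant_id[1])
    }
    sum_int <- function(cat) {
      cat <- cat[!is.na(cat)]
      if (!length(cat)) return(c(NA_real_, 0))
      s <- sum(score_ema_category(cat, midpoints))
      if (rescale_to_7_days) s <- s * 7 / length(cat)
      c(s, length(cat))
    }
    m <- sum_int(r$moderate_category)
    v <- sum_int(r$vigorous_category)
    data.frame(participant_id = r$participant_id[1],
               moderate_min_wk = m[1], vigorous_min_wk = v[1],
               mvpa_min_wk = m[1] + v[1],
               n_days_used = max(m[2], v[2]))
  })
  out <- do.call(rbind, out)
  out$instrument <- "ema"
  rownames(out) <- NULL
  out
}

#' Score BRFSS-style duration x frequency items
#'
#' Weekly minutes per intensity are the product of reported usual
#' duration (minutes/day) and frequency (times/week); MVPA is their sum
#' and is missing whenever either component is missing.
#'
#' @param responses Data frame with columns `participant_id`,
#'   `moderate_min_per_day`, `moderate_times_per_week`,
#'   `vigorous_min_per_day`, `vigorous_times_per_week` (`NA` allowed).
#' @return Per-participant weekly estimates, `instrument = "brfss"`.
#' @export
score_brfss <- function(responses) {
  need <- c("participant_id", "moderate_min_per_day",
            "moderate_times_per_week", "vigorous_min_per_day",
            "vigorous_times_per_week")
  stopifnot(all(need %in% names(responses)))
  num <- responses[setdiff(need, "participant_id")]
  if (any(unlist(num) < 0, na.rm = TRUE)) {
    stop("BRFSS durations and frequencies must be non-negative")
  }
  mod <- responses$moderate_min_per_day * responses$moderate_times_per_week
  vig <- responses$vigorous_min_per_day * responses$vigorous_times_per_week
  data.frame(participant_id = responses$participant_id,
             moderate_min_wk = mod, vigorous_min_wk = vig,
             mvpa_min_wk = mod + vig, instrument = "brfss")
}

ipaq_items <- data.frame(
  item = c("occ_vigorous", "occ_moderate", "occ_walk",
           "transport_walk", "transport_bike"),
  intensity = c("vigorous", "moderate", "moderate", "moderate", "moderate"),
  stringsAsFactors = FALSE)

#' Score IPAQ-style occupational and transport items
#'
#' Each of the five activity items reports days/week and hours/day;
#' minutes/week per item is days x hours x 60. Occupational vigorous
#' activity is vigorous; occupational moderate activity, occupational
#' walking, transport walking and transport bicycling are moderate.
#' Sitting hours (weekday/weekend items) become weekly sedentary minutes
#' via the (5 x weekday + 2 x weekend) day weighting.
#'
#' @param responses Data frame with columns `participant_id` and, for
#'   each item in `occ_vigorous`, `occ_moderate`, `occ_walk`,
#'   `transport_walk`, `transport_bike`, the pair `<item>_days` (0..7)
#'   and `<item>_hours` (hours/day), plus `sit_weekday_h` and
#'   `sit_weekend_h`.
#' @return Per-participant weekly estimates including
#'   `sedentary_min_wk`, `instrument = "ipaq"`.
#' @export
score_ipaq <- function(responses) {
  cols <- c(paste0(rep(ipaq_items$item, each = 2), c("_days", "_hours")),
            "sit_weekday_h", "sit_weekend_h")
  stopifnot(all(c("participant_id", cols) %in% names(responses)))
  days <- as.matrix(responses[paste0(ipaq_items$item, "_days")])
  hours <- as.matrix(responses[paste0(ipaq_items$item, "_hours")])
  if (any(days < 0 | days > 7, na.rm = TRUE)) stop("days must lie in 0..7")
  if (any(hours < 0, na.rm = TRUE)) stop("hours must be non-negative")
  wk <- days * hours * 60
  vig <- wk[, ipaq_items$intensity == "vigorous", drop = FALSE]
  mod <- wk[, ipaq_items$intensity == "moderate", drop = FALSE]
  vig <- rowSums(vig)
  mod <- rowSums(mod)
  sed <- (5 * responses$sit_weekday_h + 2 * responses$sit_weekend_h) * 60
  data.frame(participant_id = responses$participant_id,
             sedentary_min_wk = sed, moderate_min_wk = mod,
             vigorous_min_wk = vig, mvpa_min_wk = mod + vig,
             instrument = "ipaq")
}

#' Score screen-time sedentary items
#'
#' Television and computer hours/day, reported separately for weekdays
#' and weekend days, collapse to weekly sedentary minutes with the 5/2
#' day-type weighting. A combined report exceeding 24 h/day on either
#' day type is an impossible response and raises an error unless
#' `cap_at_week = TRUE`, in which case the weekly total is capped at
#' 10080 minutes.
#'
#' @param responses Data frame with columns `participant_id`,
#'   `tv_weekday_h`, `tv_weekend_h`, `computer_weekday_h`,
#'   `computer_weekend_h` (each in `[0, 24]`).
#' @param cap_at_week Cap impossible totals instead of erroring.
#' @return Per-participant sedentary estimates,
#'   `instrument = "screen_time"`.
#' @export
score_screen_time <- function(responses, cap_at_week = FALSE) {
  need <- c("participant_id", "tv_weekday_h", "tv_weekend_h",
            "computer_weekday_h", "computer_weekend_h")
  stopifnot(all(need %in% names(responses)))
  h <- responses[setdiff(need, "participant_id")]
  if (any(unlist(h) < 0 | unlist(h) > 24, na.rm = TRUE)) {
    stop("screen-time items must lie in [0, 24] hours/day")
  }
  wd <- responses$tv_weekday_h + responses$computer_weekday_h
  we <- responses$tv_weekend_h + responses$computer_weekend_h
  sed <- (wd * 5 + we * 2) * 60
  over <- !is.na(wd) & !is.na(we) & (wd > 24 | we > 24)
  if (any(over)) {
    if (!cap_at_week) {
      stop("combined screen time exceeds 24 h/day for participant(s) ",
           paste(responses$participant_id[over], collapse = ", "))
    }
    sed <- pmin(sed, 10080)
  }
  data.frame(participant_id = responses$participant_id,
             sedentary_min_wk = sed, instrument = "screen_time")
}

#' Assemble all instrument scores into one tidy estimates table
#'
#' @param ema,brfss,ipaq,screen Raw response tables for the four
#'   self-report instruments (any may be `NULL`).
#' @param accel_weekly Optional weekly accelerometer estimates from
#'   [process_epochs()].
#' @param midpoints EMA midpoint table.
#' @return Long data frame `participant_id`, `instrument`, `intensity`
#'   (`sedentary`, `moderate`, `vigorous`, `mvpa`), `minutes_wk`.
#' @export
score_instruments <- function(ema = NULL, brfss = NULL, ipaq = NULL,
                              screen = NULL, accel_weekly = NULL,
                              midpoints = ema_midpoints()) {
  pieces <- list()
  add <- function(df) {
    if (is.null(df)) return()
    long <- lapply(c("sedentary", "moderate", "vigorous", "mvpa"), function(int) {
      col <- paste0(int, "_min_wk")
      if (!col %in% names(df)) return(NULL)
      data.frame(participant_id = df$participant_id,
                 instrument = df$instrument, intensity = int,
                 minutes_wk = df[[col]])
    })
    pieces[[length(pieces) + 1L]] <<- do.call(rbind, long)
  }
  if (!is.null(ema)) add(score_ema_week(ema, midpoints = midpoints))
  if (!is.null(brfss)) add(score_brfss(brfss))
  if (!is.null(ipaq)) add(score_ipaq(ipaq))
  if (!is.null(screen)) add(score_screen_time(screen))
  add(accel_weekly)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
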