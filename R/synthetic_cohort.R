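#' Parameters for the synthetic validation cohort
#'
#' Defines the generating conditions for a fully synthetic
#' method-comparison study: minute-epoch activity counts with sleep and
#' nonwear zeros, planted moderate/vigorous bouts, and all four
#' self-report instruments derived from the same daily ground truth with
#' controllable reporting bias and noise. Defaults emulate the cohort
#' the pipeline targets: 238 participants wearing the device for 7
#' consecutive days, right-skewed activity volumes (daily minutes are
#' gamma-distributed within participants, with a gamma-distributed
#' activity level across participants), roughly 93% daily-diary
#' completion, daily device compliance tuned so that about 80% of
#' participants accumulate at least 4 valid wear days, and a
#' multiplicative questionnaire over-reporting bias of 3.8 so that
#' recall-questionnaire MVPA runs several-fold above device MVPA while
#' the daily diary stays close to truth.
#'
#' @param n_participants Number of participants.
#' @param n_days Observation days per participant.
#' @param seed Integer seed; fixes the whole cohort byte-for-byte.
#' @param mean_daily_moderate_min,mean_daily_vigorous_min Cohort-mean
#'   true daily minutes of moderate and vigorous activity.
#' @param activity_dispersion Gamma shape of daily minutes within a
#'   participant (smaller = more right-skewed).
#' @param between_participant_dispersion Gamma shape of the
#'   participant-level activity multiplier (mean 1).
#' @param wake_minutes_mean,wake_minutes_sd Mean and SD of the daily
#'   wake (potential wear) period, minutes; truncated to (600, 1440].
#' @param nonwear_block_rate Expected in-wake nonwear blocks per
#'   compliant day (Poisson).
#' @param nonwear_block_len_min,nonwear_block_len_max Nonwear block
#'   length bounds, minutes; at least 60 so blocks are detectable.
#' @param sedentary_frac Fraction of non-MVPA worn time that is
#'   sedentary (the rest is light activity).
#' @param ema_noise_sd SD of the Gaussian reporting noise added to true
#'   daily minutes before EMA binning, minutes.
#' @param questionnaire_bias_factor Multiplicative over-reporting bias
#'   applied to BRFSS/IPAQ weekly activity (1 = unbiased).
#' @param questionnaire_noise_cv Coefficient of variation of the
#'   mean-1 lognormal noise on questionnaire responses.
#' @param sitting_report_factor,screen_report_factor Multiplicative
#'   factors relating reported sitting / screen time to true sedentary
#'   time (< 1 reproduces the under-reporting of sedentary behavior).
#' @param ema_completion_prob Probability a daily diary is answered.
#' @param accel_compliance_prob Probability a day is worn long enough to
#'   be a valid (>= 10 h) wear day; non-compliant days carry a short
#'   worn window.
#' @param ema_midpoint_top Minutes credited to the top EMA category.
#' @return A validated `cohort_params` object.
#' @export
cohort_params <- function(n_participants = 238,
                          n_days = 7,
                          seed = 1L,
                          mean_daily_moderate_min = 22,
                          mean_daily_vigorous_min = 1.5,
                          activity_dispersion = 1.2,
                          between_participant_dispersion = 2,
                          wake_minutes_mean = 960,
                          wake_minutes_sd = 60,
                          nonwear_block_rate = 0.3,
                          nonwear_block_len_min = 60,
                          nonwear_block_len_max = 180,
                          sedentary_frac = 0.55,
                          ema_noise_sd = 10,
                          questionnaire_bias_factor = 3.8,
                          questionnaire_noise_cv = 1.5,
                          sitting_report_factor = 0.85,
                          screen_report_factor = 0.84,
                          ema_completion_prob = 0.929,
                          accel_compliance_prob = 0.65,
                          ema_midpoint_top = 70) {
  p <- as.list(environment())
  chk <- function(name, ok) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || !ok(v)) {
      stop("invalid parameter `", name, "`")
    }
  }
  pos0 <- function(v) v >= 0
  chk("n_participants", function(v) v >= 1 && v == floor(v))
  chk("n_days", function(v) v >= 1 && v == floor(v))
  chk("seed", function(v) v == floor(v))
  chk("mean_daily_moderate_min", pos0)
  chk("mean_daily_vigorous_min", pos0)
  chk("activity_dispersion", function(v) v > 0)
  chk("between_participant_dispersion", function(v) v > 0)
  chk("wake_minutes_mean", function(v) v > 600 && v <= 1440)
  chk("wake_minutes_sd", pos0)
  chk("nonwear_block_rate", pos0)
  chk("nonwear_block_len_min", function(v) v >= 60)
  chk("nonwear_block_len_max", function(v) v >= p$nonwear_block_len_min)
  chk("sedentary_frac", function(v) v >= 0 && v <= 1)
  chk("ema_noise_sd", pos0)
  chk("questionnaire_bias_factor", pos0)
  chk("questionnaire_noise_cv", pos0)
  chk("sitting_report_factor", pos0)
  chk("screen_report_factor", pos0)
  chk("ema_completion_prob", function(v) v >= 0 && v <= 1)
  chk("accel_compliance_prob", function(v) v >= 0 && v <= 1)
  chk("ema_midpoint_top", function(v) v >= 70)
  structure(p, class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("Synthetic cohort parameters: %d participants x %d days (seed %d)\n",
              x$n_participants, x$n_days, x$seed))
  cat(sprintf("  daily moderate/vigorous means: %.1f / %.1f min\n",
              x$mean_daily_moderate_min, x$mean_daily_vigorous_min))
  cat(sprintf("  questionnaire bias x%.2f (cv %.2f), EMA noise sd %.1f min\n",
              x$questionnaire_bias_factor, x$questionnaire_noise_cv,
              x$ema_noise_sd))
  cat(sprintf("  EMA completion %.1f%%, device compliance %.1f%%/day\n",
              100 * x$ema_completion_prob, 100 * x$accel_compliance_prob))
  invisible(x)
}

# count bands used when planting epochs; aligned with the default
# Freedson cut points (zeros are reserved for sleep/nonwear, so planted
# sedentary epochs use 1-99 cpm)
.bands <- list(sedentary = c(1L, 99L), light = c(100L, 1951L),
               moderate = c(1952L, 5724L), vigorous = c(5725L, 9000L))

round_to <- function(x, unit) round(x / unit) * unit

# mean-1 lognormal multiplier with the requested coefficient of variation
lognorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

rgamma_mean <- function(n, shape, mean) {
  if (mean <= 0) return(rep(0, n))
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate a fully synthetic validation cohort
#'
#' Draws per-participant activity levels and reporting-bias
#' realizations, per-day true activity minutes, minute-epoch count
#' series (sleep and nonwear as exact zeros; sedentary, light, moderate
#' and vigorous epochs drawn uniformly within their count bands), EMA
#' daily-diary categories (truth plus Gaussian noise, truncated at zero,
#' then binned), and BRFSS/IPAQ/screen-time responses (true weekly
#' minutes times the participant's multiplicative bias, rounded to each
#' item's response granularity). Identical parameters (including the
#' seed) reproduce the cohort exactly.
#'
#' @param params A [cohort_params()] object.
#' @return An object of class `pa_cohort`: list with `params`,
#'   `participants` (activity level and bias realizations), `truth`
#'   (per participant-day device-frame and behavioral minutes), `key` +
#'   `counts` (participant-day index and 1440-column count matrix),
#'   and raw response tables `ema`, `brfss`, `ipaq`, `screen`.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("params must be built with cohort_params()")
  }
  P <- params
  set.seed(P$seed)
  np <- P$n_participants
  nd <- P$n_days
  ids <- sprintf("P%04d", seq_len(np))

  level <- stats::rgamma(np, shape = P$between_participant_dispersion,
                         rate = P$between_participant_dispersion)
  participants <- data.frame(
    participant_id = ids,
    activity_level = level,
    brfss_mult = P$questionnaire_bias_factor * lognorm_mult(np, P$questionnaire_noise_cv),
    ipaq_mult = P$questionnaire_bias_factor * lognorm_mult(np, P$questionnaire_noise_cv),
    sitting_mult = P$sitting_report_factor * lognorm_mult(np, P$questionnaire_noise_cv / 4),
    screen_mult = P$screen_report_factor * lognorm_mult(np, P$questionnaire_noise_cv / 4))

  n_rows <- np * nd
  counts <- matrix(0L, nrow = n_rows, ncol = 1440L)
  truth <- data.frame(
    participant_id = rep(ids, each = nd), day = rep(seq_len(nd), np),
    compliant = FALSE, wake_min = 0L, true_wear_min = 0L,
    true_sedentary_min = 0L, true_light_min = 0L,
    true_moderate_min = 0L, true_vigorous_min = 0L,
    behav_moderate_min = 0L, behav_vigorous_min = 0L,
    behav_sedentary_min = 0L)
  ema <- data.frame(participant_id = truth$participant_id,
                    day_index = truth$day,
                    moderate_category = NA_integer_,
                    vigorous_category = NA_integer_)

  midpoints <- ema_midpoints(P$ema_midpoint_top)
  row <- 0L
  for (p in seq_len(np)) {
    for (d in seq_len(nd)) {
      row <- row + 1L
      # wake window: leading sleep >= 300 min; trailing sleep either
      # absent or >= 60 min so that every zero block is detectable
      ws <- sample(300:420, 1L)
      wl <- round(min(max(stats::rnorm(1, P$wake_minutes_mean, P$wake_minutes_sd),
                          601), 1440 - ws))
      if (1440 - (ws + wl) < 60) wl <- 1440L - ws
      wake_idx <- (ws + 1L):(ws + wl)

      compliant <- stats::runif(1) < P$accel_compliance_prob
      if (compliant) {
        worn <- wake_idx
        nb <- stats::rpois(1, P$nonwear_block_rate)
        if (nb > 0) {
          blocked <- logical(wl)
          for (b in seq_len(nb)) {
            L <- sample(P$nonwear_block_len_min:P$nonwear_block_len_max, 1L)
            if (L >= wl) next
            for (try in 1:10) {
              s <- sample(seq_len(wl - L + 1L), 1L)
              if (!any(blocked[s:(s + L - 1L)])) {
                blocked[s:(s + L - 1L)] <- TRUE
                break
              }
            }
          }
          worn <- wake_idx[!blocked]
        }
      } else {
        # short worn window: day stays below the 10-hour validity bar
        w <- round(stats::runif(1, 120, 540))
        worn <- wake_idx[seq_len(w)]
      }
      wear <- length(worn)

      mb <- round(rgamma_mean(1, P$activity_dispersion,
                              P$mean_daily_moderate_min * level[p]))
      vb <- round(rgamma_mean(1, P$activity_dispersion,
                              P$mean_daily_vigorous_min * level[p]))
      M <- min(mb, floor(0.4 * wear))
      V <- min(vb, floor(0.2 * wear))

      # quasi-contiguous bouts: consecutive in worn-minute order,
      # starting at a random wake-time offset
      o <- sample.int(wear, 1L)
      pos <- worn[((o + seq_len(M + V) - 2L) %% wear) + 1L]
      mod_idx <- pos[seq_len(M)]
      vig_idx <- pos[M + seq_len(V)]
      rest <- setdiff(worn, pos)
      sed_n <- round(P$sedentary_frac * length(rest))
      sed_idx <- if (sed_n > 0) rest[sample.int(length(rest), sed_n)] else integer(0)
      light_idx <- setdiff(rest, sed_idx)

      x <- integer(1440L)
      band <- function(idx, b) {
        if (length(idx)) x[idx] <<- sample(b[1]:b[2], length(idx), replace = TRUE)
      }
      band(sed_idx, .bands$sedentary)
      band(light_idx, .bands$light)
      band(mod_idx, .bands$moderate)
      band(vig_idx, .bands$vigorous)
      counts[row, ] <- x

      truth$compliant[row] <- compliant
      truth$wake_min[row] <- wl
      truth$true_wear_min[row] <- wear
      truth$true_sedentary_min[row] <- sed_n
      truth$true_light_min[row] <- length(rest) - sed_n
      truth$true_moderate_min[row] <- M
      truth$true_vigorous_min[row] <- V
      truth$behav_moderate_min[row] <- mb
      truth$behav_vigorous_min[row] <- vb
      truth$behav_sedentary_min[row] <- round(P$sedentary_frac * (wl - mb - vb))

      if (stats::runif(1) < P$ema_completion_prob) {
        noise <- if (P$ema_noise_sd > 0) stats::rnorm(2, 0, P$ema_noise_sd) else c(0, 0)
        ema$moderate_category[row] <- bin_ema_minutes(max(0, mb + noise[1]))
        ema$vigorous_category[row] <- bin_ema_minutes(max(0, vb + noise[2]))
      }
    }
  }

  week_scale <- 7 / nd
  wk <- function(col) {
    tapply(truth[[col]], truth$participant_id, sum)[ids] * week_scale
  }
  wm <- as.numeric(wk("behav_moderate_min"))
  wv <- as.numeric(wk("behav_vigorous_min"))
  wsed <- as.numeric(wk("behav_sedentary_min"))

  brfss <- make_brfss(ids, wm * participants$brfss_mult,
                      wv * participants$brfss_mult)
  ipaq <- make_ipaq(ids, wm * participants$ipaq_mult,
                    wv * participants$ipaq_mult,
                    wsed * participants$sitting_mult)
  screen <- make_screen(ids, wsed * participants$screen_mult)

  structure(list(params = P, participants = participants, truth = truth,
                 key = truth[, c("participant_id", "day")],
                 counts = counts, ema = ema, brfss = brfss, ipaq = ipaq,
                 screen = screen),
            class = "pa_cohort")
}

# decompose a weekly minutes target into duration x frequency items
# (minutes/day on a 5-minute grid, capped at 1440)
make_brfss <- function(ids, wm, wv) {
  one <- function(w) {
    t <- ifelse(w > 0, sample(1:7, length(w), replace = TRUE), 0L)
    mpd <- ifelse(t > 0, pmin(round_to(w / pmax(t, 1), 5), 1440), 0)
    list(t = t, mpd = mpd)
  }
  m <- one(wm); v <- one(wv)
  data.frame(participant_id = ids,
             moderate_min_per_day = m$mpd, moderate_times_per_week = m$t,
             vigorous_min_per_day = v$mpd, vigorous_times_per_week = v$t)
}

# spread weekly moderate minutes over the four moderate IPAQ items and
# vigorous over the occupational vigorous item (hours on a 0.25-h grid);
# sitting items on a 0.5-h grid with the weekend slightly above the
# weekday so the 5/2-weighted mean equals the target
make_ipaq <- function(ids, wm, wv, wsed) {
  n <- length(ids)
  item <- function(w) {
    d <- ifelse(w > 0, sample(1:7, n, replace = TRUE), 0L)
    h <- ifelse(d > 0, pmin(round_to(w / (60 * pmax(d, 1)), 0.25), 24), 0)
    list(d = d, h = h)
  }
  split4 <- matrix(stats::runif(4 * n), nrow = n)
  split4 <- split4 / rowSums(split4)
  parts <- lapply(1:4, function(j) item(wm * split4[, j]))
  vigi <- item(wv)
  sit_h <- wsed / 7 / 60
  out <- data.frame(participant_id = ids,
                    occ_vigorous_days = vigi$d, occ_vigorous_hours = vigi$h,
                    occ_moderate_days = parts[[1]]$d, occ_moderate_hours = parts[[1]]$h,
                    occ_walk_days = parts[[2]]$d, occ_walk_hours = parts[[2]]$h,
                    transport_walk_days = parts[[3]]$d, transport_walk_hours = parts[[3]]$h,
                    transport_bike_days = parts[[4]]$d, transport_bike_hours = parts[[4]]$h,
                    sit_weekday_h = pmin(round_to(sit_h * 0.96, 0.5), 24),
                    sit_weekend_h = pmin(round_to(sit_h * 1.1, 0.5), 24))
  out
}

# weekly screen minutes -> tv/computer x weekday/weekend hours on a
# 0.5-h grid, rescaled when a day type would exceed 24 h
make_screen <- function(ids, wk_min) {
  daily_h <- wk_min / 7 / 60
  wd <- daily_h * 0.96
  we <- daily_h * 1.1
  scale <- pmax(1, wd / 24, we / 24)
  wd <- wd / scale; we <- we / scale
  tv_share <- stats::runif(length(ids), 0.4, 0.8)
  data.frame(participant_id = ids,
             tv_weekday_h = round_to(wd * tv_share, 0.5),
             tv_weekend_h = round_to(we * tv_share, 0.5),
             computer_weekday_h = round_to(wd * (1 - tv_share), 0.5),
             computer_weekend_h = round_to(we * (1 - tv_share), 0.5))
}

#' @export
print.pa_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d days (seed %d)\n",
              x$params$n_participants, x$params$n_days, x$params$seed))
  cat(sprintf("  %d participant-days of 1440-epoch counts; %.1f%% diaries answered\n",
              nrow(x$truth), 100 * mean(!is.na(x$ema$moderate_category))))
  invisible(x)
}

#' Per-participant weekly ground truth
#'
#' Behavioral weekly minutes (what the questionnaires report on) and
#' device-frame weekly truth restricted to worn time, both rescaled to a
#' 7-day week when `n_days != 7`.
#'
#' @param cohort A `pa_cohort` object.
#' @return Data frame keyed by `participant_id`.
#' @export
truth_weekly <- function(cohort) {
  stopifnot(inherits(cohort, "pa_cohort"))
  tr <- cohort$truth
  f <- 7 / cohort$params$n_days
  agg <- function(col) as.numeric(tapply(tr[[col]], tr$participant_id, sum))
  ids <- sort(unique(tr$participant_id))
  data.frame(participant_id = ids,
             behav_moderate_min_wk = agg("behav_moderate_min") * f,
             behav_vigorous_min_wk = agg("behav_vigorous_min") * f,
             behav_mvpa_min_wk = (agg("behav_moderate_min") +
                                  agg("behav_vigorous_min")) * f,
             behav_sedentary_min_wk = agg("behav_sedentary_min") * f,
             true_moderate_min_wk = agg("true_moderate_min") * f,
             true_vigorous_min_wk = agg("true_vigorous_min") * f,
             true_sedentary_min_wk = agg("true_sedentary_min") * f)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the epoch dialect (`participant_id,day,minute,counts`), the
#' four raw response tables, the daily truth table and the participant
#' bias realizations. Column meanings are listed in the data dictionary
#' shipped at `system.file("extdata", "data_dictionary.csv",
#' package = "paconcord")`.
#'
#' @param cohort A `pa_cohort` object.
#' @param dir Output directory (created if needed).
#' @param epochs Write the (large) epoch CSV too?
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, epochs = TRUE) {
  stopifnot(inherits(cohort, "pa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (epochs) {
    long <- data.frame(
      participant_id = rep(cohort$key$participant_id, each = 1440L),
      day = rep(cohort$key$day, each = 1440L),
      minute = rep(0:1439, nrow(cohort$key)),
      counts = as.integer(t(cohort$counts)))
    put(long, "epochs.csv")
  }
  put(cohort$ema, "ema.csv")
  put(cohort$brfss, "brfss.csv")
  put(cohort$ipaq, "ipaq.csv")
  put(cohort$screen, "screen_time.csv")
  put(cohort$truth, "truth_daily.csv")
  put(cohort$participants, "participants.csv")
  invisible(files)
}
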