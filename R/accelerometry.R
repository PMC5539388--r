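#' Freedson adult activity-count cut points
#'
#' Counts-per-minute thresholds mapping 60-second epochs to intensity
#' categories. Defaults are the standard adult thresholds: sedentary
#' 0-99 cpm, light 100-1951, moderate 1952-5724, vigorous >= 5725.
#'
#' @param sedentary_max Upper cpm bound of the sedentary band.
#' @param light_max Upper cpm bound of the light band.
#' @param moderate_max Upper cpm bound of the moderate band; everything
#'   above is vigorous.
#' @return An object of class `cut_points`.
#' @export
#' @examples
#' freedson_cut_points()
freedson_cut_points <- function(sedentary_max = 99, light_max = 1951,
                                moderate_max = 5724) {
  stopifnot(is.numeric(sedentary_max), is.numeric(light_max),
            is.numeric(moderate_max))
  if (!(0 <= sedentary_max && sedentary_max < light_max &&
        light_max < moderate_max)) {
    stop("cut points must satisfy 0 <= sedentary_max < light_max < moderate_max")
  }
  structure(list(sedentary_max = sedentary_max, light_max = light_max,
                 moderate_max = moderate_max),
            class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  cat("Activity-count cut points (cpm):\n")
  cat(sprintf("  sedentary: 0-%g\n  light: %g-%g\n  moderate: %g-%g\n  vigorous: >= %g\n",
              x$sedentary_max, x$sedentary_max + 1, x$light_max,
              x$light_max + 1, x$moderate_max, x$moderate_max + 1))
  invisible(x)
}

check_epoch_day <- function(counts) {
  if (!is.numeric(counts) || length(counts) != 1440L) {
    stop("an epoch day must be a numeric vector of exactly 1440 counts")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("epoch counts must be non-negative integers with no missing values")
  }
  invisible(counts)
}

#' Detect accelerometer nonwear time in a minute-epoch day
#'
#' Implements the Troiano-style screening rule: nonwear is any maximal
#' window of at least `zero_run_min` minutes consisting of zero counts,
#' allowing interruptions of at most `allowance_max_epochs` consecutive
#' epochs each with counts in `(0, allowance_cpm_max]`. An epoch above
#' `allowance_cpm_max`, or a run of more than `allowance_max_epochs`
#' consecutive nonzero epochs, terminates the window; a window always
#' starts and ends on a zero epoch. Wear is the complement.
#'
#' The scan is run-length based: zero runs are merged across admissible
#' interruptions and the merged zero-bounded spans of sufficient length
#' are flagged.
#'
#' @param counts Vector of non-negative integer epoch counts (1440 for
#'   a full day; any positive length is accepted, the rule is
#'   length-agnostic).
#' @param zero_run_min Minimum window length, minutes.
#' @param allowance_max_epochs Maximum consecutive nonzero epochs
#'   tolerated inside a window.
#' @param allowance_cpm_max Maximum cpm an interruption epoch may carry.
#' @return Logical vector matching `counts`; `TRUE` = worn.
#' @export
detect_nonwear <- function(counts, zero_run_min = 60,
                           allowance_max_epochs = 2,
                           allowance_cpm_max = 100) {
  if (!is.numeric(counts) || !length(counts) || anyNA(counts) ||
      any(counts < 0) || any(counts != floor(counts))) {
    stop("epoch counts must be non-negative integers with no missing values")
  }
  n <- length(counts)
  worn <- rep(TRUE, n)
  z <- counts == 0
  if (!any(z)) return(worn)

  r <- rle(z)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a nonzero run is admissible as an interior interruption iff it is
  # short enough and every epoch stays at or below the allowance cpm
  run_max <- vapply(seq_len(k), function(i) {
    if (r$values[i]) 0 else max(counts[starts[i]:ends[i]])
  }, numeric(1))
  admissible <- !r$values & r$lengths <= allowance_max_epochs &
    run_max <= allowance_cpm_max

  i <- 1L
  while (i <= k) {
    if (!r$values[i]) { i <- i + 1L; next }
    # open a window at this zero run; absorb (admissible nonzero, zero)
    # pairs while possible
    j <- i
    while (j + 2L <= k && admissible[j + 1L] && r$values[j + 2L]) {
      j <- j + 2L
    }
    if (ends[j] - starts[i] + 1L >= zero_run_min) {
      worn[starts[i]:ends[j]] <- FALSE
    }
    i <- j + 1L
  }
  worn
}

#' Classify worn epochs into intensity categories for one day
#'
#' Each worn epoch is assigned exactly one intensity by its count band;
#' nonwear epochs are counted nowhere. A day is valid when wear time
#' meets `min_wear_min` (default 600 minutes = 10 hours).
#'
#' @param counts Integer vector of 1440 epoch counts.
#' @param mask Logical wear mask as returned by [detect_nonwear()].
#' @param cuts A [freedson_cut_points()] object.
#' @param min_wear_min Minimum wear minutes for a valid day.
#' @return One-row data frame: `wear_min`, `sedentary_min`, `light_min`,
#'   `moderate_min`, `vigorous_min`, `valid`.
#' @export
classify_epochs <- function(counts, mask, cuts = freedson_cut_points(),
                            min_wear_min = 600) {
  check_epoch_day(counts)
  if (!is.logical(mask) || length(mask) != length(counts) || anyNA(mask)) {
    stop("mask must be a logical vector matching the epoch day length")
  }
  worn <- counts[mask]
  wear <- length(worn)
  sed <- sum(worn <= cuts$sedentary_max)
  light <- sum(worn > cuts$sedentary_max & worn <= cuts$light_max)
  mod <- sum(worn > cuts$light_max & worn <= cuts$moderate_max)
  vig <- sum(worn > cuts$moderate_max)
  data.frame(wear_min = wear, sedentary_min = sed, light_min = light,
             moderate_min = mod, vigorous_min = vig,
             valid = wear >= min_wear_min)
}

#' One-call daily summary: nonwear screening plus classification
#'
#' @inheritParams classify_epochs
#' @param ... Passed to [detect_nonwear()].
#' @export
daily_summary <- function(counts, cuts = freedson_cut_points(),
                          min_wear_min = 600, ...) {
  classify_epochs(counts, detect_nonwear(counts, ...), cuts = cuts,
                  min_wear_min = min_wear_min)
}

#' Weekly accelerometer estimate from daily summaries
#'
#' Participants with fewer than `min_valid_days` valid days are excluded
#' (the estimate is missing, feeding the complete-case comparisons).
#' Otherwise each intensity's weekly value is the mean over valid days
#' scaled to a 7-day week (`day_mean_x7`, the default) or the plain sum
#' over valid days (`sum_valid`). Sedentary minutes count worn sedentary
#' epochs only: nonwear is not sedentary time.
#'
#' @param daily Data frame of daily summaries ([classify_epochs()] rows).
#' @param min_valid_days Minimum number of valid days required.
#' @param scale `"day_mean_x7"` or `"sum_valid"`.
#' @return One-row data frame: `sedentary_min_wk`, `moderate_min_wk`,
#'   `vigorous_min_wk`, `mvpa_min_wk`, `n_days_used` (all `NA` but
#'   `n_days_used` when the participant is excluded).
#' @export
weekly_accel_estimate <- function(daily, min_valid_days = 4,
                                  scale = c("day_mean_x7", "sum_valid")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(daily), nrow(daily) <= 7)
  valid <- daily[daily$valid, , drop = FALSE]
  nv <- nrow(valid)
  if (nv < min_valid_days) {
    return(data.frame(sedentary_min_wk = NA_real_, moderate_min_wk = NA_real_,
                      vigorous_min_wk = NA_real_, mvpa_min_wk = NA_real_,
                      n_days_used = nv))
  }
  f <- function(v) if (scale == "day_mean_x7") mean(v) * 7 else sum(v)
  sed <- f(valid$sedentary_min)
  mod <- f(valid$moderate_min)
  vig <- f(valid$vigorous_min)
  data.frame(sedentary_min_wk = sed, moderate_min_wk = mod,
             vigorous_min_wk = vig, mvpa_min_wk = mod + vig,
             n_days_used = nv)
}

#' Process a cohort of minute-epoch days into daily and weekly summaries
#'
#' @param epochs Either a long data frame with columns `participant_id`,
#'   `day`, `minute` (0-1439) and `counts`, or a list with an integer
#'   matrix `counts` (one row per participant-day, 1440 columns) and a
#'   data frame `key` carrying `participant_id` and `day` per row (the
#'   compact form produced by [generate_cohort()]).
#' @param cuts A [freedson_cut_points()] object.
#' @param min_wear_min Minimum wear minutes for a valid day.
#' @param min_valid_days Minimum valid days for a weekly estimate.
#' @param scale Weekly scaling rule, see [weekly_accel_estimate()].
#' @return List with `daily` (per participant-day) and `weekly`
#'   (per participant, `instrument = "accelerometer"`) data frames.
#' @export
process_epochs <- function(epochs, cuts = freedson_cut_points(),
                           min_wear_min = 600, min_valid_days = 4,
                           scale = "day_mean_x7") {
  if (is.data.frame(epochs)) {
    need <- c("participant_id", "day", "minute", "counts")
    if (!all(need %in% names(epochs))) {
      stop("epoch data frame must have columns: ",
           paste(need, collapse = ", "))
    }
    o <- order(epochs$participant_id, epochs$day, epochs$minute)
    epochs <- epochs[o, , drop = FALSE]
    key <- unique(epochs[, c("participant_id", "day")])
    if (nrow(epochs) != 1440L * nrow(key)) {
      stop("every participant-day must contribute exactly 1440 epochs")
    }
    mat <- matrix(as.integer(epochs$counts), ncol = 1440L, byrow = TRUE)
  } else {
    mat <- epochs$counts
    key <- epochs$key
    stopifnot(is.matrix(mat), ncol(mat) == 1440L, nrow(mat) == nrow(key))
  }

  sums <- vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    worn <- x[detect_nonwear(x)]
    c(length(worn),
      sum(worn <= cuts$sedentary_max),
      sum(worn > cuts$sedentary_max & worn <= cuts$light_max),
      sum(worn > cuts$light_max & worn <= cuts$moderate_max),
      sum(worn > cuts$moderate_max))
  }, numeric(5))
  daily <- data.frame(participant_id = key$participant_id, day = key$day,
                      wear_min = sums[1, ], sedentary_min = sums[2, ],
                      light_min = sums[3, ], moderate_min = sums[4, ],
                      vigorous_min = sums[5, ],
                      valid = sums[1, ] >= min_wear_min)

  weekly <- do.call(rbind, lapply(split(daily, daily$participant_id),
    function(d) {
      w <- weekly_accel_estimate(d, min_valid_days = min_valid_days,
                                 scale = scale)
      cbind(data.frame(participant_id = d$participant_id[1]), w)
    }))
  weekly$instrument <- "accelerometer"
  rownames(weekly) <- NULL
  list(daily = daily, weekly = weekly)
}

#' Read a minute-epoch CSV
#'
#' Accepts the cohort dialect (`participant_id,day,minute,counts`) or a
#' two-column `timestamp,counts` per-participant export (60-s epochs),
#' for which the participant id is taken from `participant_id` or the
#' file name.
#'
#' @param path CSV path.
#' @param participant_id Id used for the two-column dialect; defaults to
#'   the file base name.
#' @return Long epoch data frame as consumed by [process_epochs()].
#' @export
read_epoch_csv <- function(path, participant_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("participant_id", "day", "minute", "counts") %in% names(df))) {
    return(df)
  }
  if (all(c("timestamp", "counts") %in% names(df))) {
    ts <- as.POSIXct(df$timestamp, tz = "UTC")
    if (anyNA(ts)) stop("unparseable timestamps in ", path)
    if (is.null(participant_id)) {
      participant_id <- sub("\\.[^.]*$", "", basename(path))
    }
    day <- as.integer(as.Date(ts) - min(as.Date(ts))) + 1L
    minute <- as.integer(format(ts, "%H")) * 60L + as.integer(format(ts, "%M"))
    return(data.frame(participant_id = participant_id, day = day,
                      minute = minute, counts = df$counts))
  }
  stop("unrecognised epoch CSV dialect in ", path)
}
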