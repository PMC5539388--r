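#' Study configuration
#'
#' Bundles every tunable of a run: synthetic-cohort parameters (or input
#' paths for file mode), cut points, wear-time validity thresholds, the
#' EMA midpoint table and agreement options. A configuration plus its
#' seed determines the whole report bundle.
#'
#' @param params A [cohort_params()] object (synthetic mode), or `NULL`
#'   when reading files.
#' @param epochs_path,surveys_dir Input locations for file mode:
#'   an epoch CSV and a directory holding `ema.csv`, `brfss.csv`,
#'   `ipaq.csv`, `screen_time.csv` (any may be absent).
#' @param cuts A [freedson_cut_points()] object.
#' @param min_wear_hours Valid-day wear threshold, hours.
#' @param min_valid_days Valid days required for a device estimate.
#' @param ema_midpoint_top Minutes credited to the top EMA category.
#' @param ba_offset Additive offset for the log Bland-Altman transform.
#' @param holm_family Holm family definition, `"intensity"` or `"all"`.
#' @param ci_level Confidence level for concordance CIs.
#' @param weekly_scale Device weekly scaling, see
#'   [weekly_accel_estimate()].
#' @param seed Integer seed (overrides `params$seed` in synthetic mode).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `study_config` object.
#' @export
study_config <- function(params = cohort_params(), epochs_path = NULL,
                         surveys_dir = NULL, cuts = freedson_cut_points(),
                         min_wear_hours = 10, min_valid_days = 4,
                         ema_midpoint_top = 70, ba_offset = 1,
                         holm_family = "intensity", ci_level = 0.95,
                         weekly_scale = "day_mean_x7", seed = NULL,
                         out_dir = NULL) {
  stopifnot(min_wear_hours > 0, min_valid_days > 0,
            ci_level > 0, ci_level < 1, ba_offset >= 0)
  if (is.null(params) && is.null(epochs_path)) {
    stop("provide synthetic `params` or an `epochs_path`")
  }
  if (!is.null(epochs_path) && !file.exists(epochs_path)) {
    stop("epochs_path does not exist: ", epochs_path)
  }
  if (!is.null(surveys_dir) && !dir.exists(surveys_dir)) {
    stop("surveys_dir does not exist: ", surveys_dir)
  }
  if (!is.null(params) && !is.null(seed)) {
    args <- unclass(params)
    args$seed <- as.integer(seed)
    params <- do.call(cohort_params, args)
  }
  structure(list(params = params, epochs_path = epochs_path,
                 surveys_dir = surveys_dir, cuts = cuts,
                 min_wear_hours = min_wear_hours,
                 min_valid_days = min_valid_days,
                 ema_midpoint_top = ema_midpoint_top,
                 ba_offset = ba_offset, holm_family = holm_family,
                 ci_level = ci_level, weekly_scale = weekly_scale,
                 seed = if (is.null(seed) && !is.null(params)) params$seed
                        else seed,
                 out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the [study_config()] arguments; `params` and
#' `cuts` are nested maps passed to [cohort_params()] and
#' [freedson_cut_points()].
#'
#' @param path YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$params)) args$params <- do.call(cohort_params, y$params)
  if (!is.null(y$cuts)) args$cuts <- do.call(freedson_cut_points, y$cuts)
  do.call(study_config, args)
}

read_surveys <- function(dir) {
  grab <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  list(ema = grab("ema.csv"), brfss = grab("brfss.csv"),
       ipaq = grab("ipaq.csv"), screen = grab("screen_time.csv"))
}

#' Run the full validation study
#'
#' Orchestrates generate (or load) -> device processing -> instrument
#' scoring -> descriptives -> correlation, concordance, Bland-Altman and
#' over-reporting tables, and writes the report bundle as CSVs plus a
#' JSON run manifest when `config$out_dir` is set. Identical config and
#' seed reproduce the bundle byte for byte.
#'
#' @param config A [study_config()] object.
#' @return Invisibly, a list with `estimates`, `daily`, `descriptives`,
#'   `correlations`, `agreement`, `bland_altman`, `overreporting`,
#'   `manifest` (and `cohort` in synthetic mode).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- NULL
  if (!is.null(config$params)) {
    cohort <- generate_cohort(config$params)
    epochs <- list(counts = cohort$counts, key = cohort$key)
    surveys <- list(ema = cohort$ema, brfss = cohort$brfss,
                    ipaq = cohort$ipaq, screen = cohort$screen)
  } else {
    epochs <- read_epoch_csv(config$epochs_path)
    surveys <- if (is.null(config$surveys_dir)) {
      list(ema = NULL, brfss = NULL, ipaq = NULL, screen = NULL)
    } else read_surveys(config$surveys_dir)
  }

  proc <- process_epochs(epochs, cuts = config$cuts,
                         min_wear_min = config$min_wear_hours * 60,
                         min_valid_days = config$min_valid_days,
                         scale = config$weekly_scale)
  estimates <- score_instruments(
    ema = surveys$ema, brfss = surveys$brfss, ipaq = surveys$ipaq,
    screen = surveys$screen, accel_weekly = proc$weekly,
    midpoints = ema_midpoints(config$ema_midpoint_top))

  desc <- describe_estimates(estimates)
  corr <- correlation_table(estimates, family = config$holm_family)
  agr <- agreement_table(estimates, ci_level = config$ci_level)
  ba <- bland_altman_table(estimates, offset = config$ba_offset)
  over <- overreporting_summary(estimates)

  n_part <- length(unique(proc$weekly$participant_id))
  n_device_ok <- sum(!is.na(proc$weekly$mvpa_min_wk))
  n_days <- if (!is.null(config$params)) config$params$n_days else
    max(proc$daily$day)
  diary_possible <- count_diary_slots(n_part, n_days)
  diary_answered <- if (!is.null(surveys$ema)) {
    sum(!is.na(surveys$ema$moderate_category) |
        !is.na(surveys$ema$vigorous_category))
  } else NA_integer_
  manifest <- list(
    package_version = as.character(utils::packageVersion("paconcord")),
    seed = config$seed,
    mode = if (is.null(config$params)) "files" else "synthetic",
    n_participants = n_part,
    n_days = n_days,
    diary_slots_possible = diary_possible,
    diary_slots_answered = diary_answered,
    diary_completion_pct = if (is.na(diary_answered)) NA else
      100 * diary_answered / diary_possible,
    n_device_compliant = n_device_ok,
    n_device_excluded = n_part - n_device_ok,
    min_wear_hours = config$min_wear_hours,
    min_valid_days = config$min_valid_days,
    weekly_scale = config$weekly_scale,
    holm_family = config$holm_family,
    ba_offset = config$ba_offset,
    ci_level = config$ci_level)
  if (n_device_ok == 0) {
    message("no participant met the ", config$min_valid_days,
            "-valid-day device threshold; device comparisons are empty")
  }

  bundle <- list(estimates = estimates, daily = proc$daily,
                 descriptives = desc, correlations = corr, agreement = agr,
                 bland_altman = ba, overreporting = over,
                 manifest = manifest, cohort = cohort)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     na = "NA")
  }
  put(bundle$estimates, "estimates.csv")
  put(bundle$daily, "daily_summaries.csv")
  put(bundle$descriptives, "descriptives.csv")
  put(bundle$correlations, "correlations.csv")
  put(bundle$agreement, "agreement.csv")
  put(bundle$bland_altman$summary, "bland_altman_summary.csv")
  put(bundle$bland_altman$points, "bland_altman_points.csv")
  put(bundle$overreporting, "overreporting.csv")
  # concordance plot coordinates: instrument value against device value
  if (!is.null(bundle$estimates)) {
    cc <- do.call(rbind, lapply(
      setdiff(unique(bundle$estimates$instrument), "accelerometer"),
      function(inst) {
        pr <- complete_case_pairs(bundle$estimates, inst, "accelerometer",
                                  "mvpa")
        if (!pr$n) return(NULL)
        data.frame(instrument = inst, participant_id = pr$participant_id,
                   instrument_min_wk = pr$x, device_min_wk = pr$y)
      }))
    put(cc, "concordance_points.csv")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
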