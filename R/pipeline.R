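#' Number of possible daily-diary assessments in a study
#'
#' @param n_participants,n_days Cohort dimensions.
#' @return `n_participants * n_days`.
#' @export
#' @examples
#' count_diary_slots(238, 7)  # 1666
count_diary_slots <- function(n_participants, n_days) {
  stopifnot(n_participants >= 0, n_days >= 0)
  as.integer(n_participants) * as.integer(n_days)
}

#' Screening yield summary
#'
#' @param screened Number screened for eligibility.
#' @param enrolled Number enrolled.
#' @return List with `screened`, `enrolled` and `pct_eligible`
#'   (percentage, 0-100).
#' @export
screening_summary <- function(screened, enrolled) {
  stopifnot(screened > 0, enrolled >= 0, enrolled <= screened)
  list(screened = screened, enrolled = enrolled,
       pct_eligible = 100 * enrolled / screened)
}

#' Descriptive summary of one estimate vector
#'
#' Mean, sample SD, 25th/50th/75th percentiles (linear interpolation
#' between order statistics) and a Shapiro-Wilk normality p-value.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param label Variable label carried into the row.
#' @return One-row data frame (`DescriptiveRow`): `variable`, `n`,
#'   `mean`, `sd`, `p25`, `p50`, `p75`, `shapiro_p` (`NA` with a warning
#'   for constant vectors; `NA` when n < 3).
#' @export
descriptives <- function(values, label = "") {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to describe")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sw <- NA_real_
  if (length(values) >= 3) {
    if (stats::sd(values) == 0) {
      warning("constant vector: Shapiro-Wilk omitted")
    } else {
      n_sw <- length(values)
      sw_values <- if (n_sw > 5000) values[seq_len(5000)] else values
      sw <- stats::shapiro.test(sw_values)$p.value
    }
  }
  data.frame(variable = label, n = length(values), mean = mean(values),
             sd = stats::sd(values), p25 = q[1], p50 = q[2], p75 = q[3],
             shapiro_p = sw)
}

#' Descriptive table over all instrument x intensity cells
#'
#' @param estimates Tidy estimates table (`participant_id`,
#'   `instrument`, `intensity`, `minutes_wk`).
#' @return Data frame of [descriptives()] rows, one per cell with data.
#' @export
describe_estimates <- function(estimates) {
  check_estimates(estimates)
  cells <- unique(estimates[, c("intensity", "instrument")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    v <- estimates$minutes_wk[estimates$intensity == cells$intensity[i] &
                              estimates$instrument == cells$instrument[i]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    cbind(cells[i, , drop = FALSE],
          descriptives(v, paste(cells$instrument[i], cells$intensity[i]))[-1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

check_estimates <- function(estimates) {
  need <- c("participant_id", "instrument", "intensity", "minutes_wk")
  if (!is.data.frame(estimates) || !all(need %in% names(estimates))) {
    stop("estimates must be a tidy table with columns: ",
         paste(need, collapse = ", "))
  }
  invisible(estimates)
}

#' Complete-case paired sample for two instruments
#'
#' Restricts to participants with both values present (each pairwise
#' comparison uses its own complete cases, so n differs across cells).
#'
#' @param estimates Tidy estimates table.
#' @param instrument_a,instrument_b Instrument names.
#' @param intensity Intensity row (`sedentary`, `moderate`, `vigorous`,
#'   `mvpa`).
#' @return List with `x` (instrument_a), `y` (instrument_b), `n`,
#'   `participant_id`.
#' @export
complete_case_pairs <- function(estimates, instrument_a, instrument_b,
                                intensity) {
  check_estimates(estimates)
  pick <- function(inst) {
    e <- estimates[estimates$instrument == inst &
                   estimates$intensity == intensity, ]
    stats::setNames(e$minutes_wk, e$participant_id)
  }
  a <- pick(instrument_a)
  b <- pick(instrument_b)
  ids <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  ids <- sort(ids)
  list(x = unname(a[ids]), y = unname(b[ids]), n = length(ids),
       participant_id = ids)
}

#' Spearman correlation table with Holm step-down decisions
#'
#' Every pair of instruments is correlated within each intensity on its
#' complete cases. Holm's adjustment is applied per family:
#' `"intensity"` (default) treats each intensity's set of pairwise
#' p-values as one family; `"all"` pools the whole table.
#'
#' @param estimates Tidy estimates table.
#' @param alpha Family-wise error level.
#' @param family `"intensity"` or `"all"`.
#' @param min_n Smallest complete-case n for which a correlation is
#'   attempted.
#' @return Data frame: `intensity`, `instrument_a`, `instrument_b`, `n`,
#'   `rho`, `p`, `holm_significant`.
#' @export
correlation_table <- function(estimates, alpha = 0.05,
                              family = c("intensity", "all"), min_n = 3) {
  check_estimates(estimates)
  family <- match.arg(family)
  rows <- list()
  for (int in unique(estimates$intensity)) {
    insts <- unique(estimates$instrument[estimates$intensity == int &
                                         !is.na(estimates$minutes_wk)])
    if (length(insts) < 2) next
    for (i in seq_along(insts)) for (j in seq_along(insts)) {
      if (i >= j) next
      pr <- complete_case_pairs(estimates, insts[i], insts[j], int)
      if (pr$n < min_n || stats::sd(pr$x) == 0 || stats::sd(pr$y) == 0) {
        sp <- list(rho = NA_real_, p = NA_real_, n = pr$n)
      } else {
        sp <- spearman_cor(pr$x, pr$y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        intensity = int, instrument_a = insts[i], instrument_b = insts[j],
        n = pr$n, rho = sp$rho, p = sp$p)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (family == "all") {
    out$holm_significant <- holm_adjust(out$p, alpha)
  } else {
    out$holm_significant <- NA
    for (int in unique(out$intensity)) {
      sel <- out$intensity == int
      out$holm_significant[sel] <- holm_adjust(out$p[sel], alpha)
    }
  }
  rownames(out) <- NULL
  out
}

#' Concordance table: each instrument against the device
#'
#' Lin's concordance correlation with 95% CI, Pearson r with its
#' p-value, and the bias correction factor, per instrument x intensity
#' cell on that cell's complete cases.
#'
#' @param estimates Tidy estimates table.
#' @param device Reference instrument (default `"accelerometer"`).
#' @param ci_level Confidence level for the concordance CI.
#' @param min_n Smallest complete-case n attempted.
#' @return Data frame: `intensity`, `instrument`, `n`, `lcc`, `ci_low`,
#'   `ci_high`, `pearson_r`, `pearson_p`, `bcf`.
#' @export
agreement_table <- function(estimates, device = "accelerometer",
                            ci_level = 0.95, min_n = 3) {
  check_estimates(estimates)
  rows <- list()
  for (int in unique(estimates$intensity)) {
    insts <- setdiff(unique(estimates$instrument[estimates$intensity == int &
                                                 !is.na(estimates$minutes_wk)]),
                     device)
    for (inst in insts) {
      pr <- complete_case_pairs(estimates, inst, device, int)
      if (pr$n < min_n || stats::sd(pr$x) == 0 || stats::sd(pr$y) == 0) {
        cc <- list(n = pr$n, lcc = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, pearson_r = NA_real_,
                   pearson_p = NA_real_, bcf = NA_real_)
      } else {
        cc <- lin_ccc(pr$x, pr$y, ci_level = ci_level)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        intensity = int, instrument = inst, n = pr$n, lcc = cc$lcc,
        ci_low = cc$ci_low, ci_high = cc$ci_high,
        pearson_r = cc$pearson_r, pearson_p = cc$pearson_p, bcf = cc$bcf)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman summaries and plot coordinates versus the device
#'
#' @param estimates Tidy estimates table.
#' @param intensity Intensity compared (default `"mvpa"`, the headline
#'   comparison).
#' @param device Reference instrument.
#' @param offset Additive constant before the log transform.
#' @return List with `summary` (per instrument: n, mean difference and
#'   limits of agreement in log units) and `points` (per-pair plot
#'   coordinates with instrument labels).
#' @export
bland_altman_table <- function(estimates, intensity = "mvpa",
                               device = "accelerometer", offset = 1) {
  check_estimates(estimates)
  insts <- setdiff(unique(estimates$instrument[estimates$intensity == intensity &
                                               !is.na(estimates$minutes_wk)]),
                   device)
  summaries <- list(); points <- list()
  for (inst in insts) {
    pr <- complete_case_pairs(estimates, inst, device, intensity)
    if (pr$n < 3) next
    ba <- bland_altman_log(pr$x, pr$y, offset = offset)
    summaries[[length(summaries) + 1L]] <- data.frame(
      instrument = inst, n = pr$n, mean_diff = ba$mean_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high)
    points[[length(points) + 1L]] <- cbind(
      data.frame(instrument = inst, participant_id = pr$participant_id),
      ba$points)
  }
  list(summary = do.call(rbind, summaries), points = do.call(rbind, points))
}

#' Mean over-reporting of each instrument relative to the device
#'
#' Difference of cohort means (instrument minus device), each mean taken
#' over that instrument's own non-missing values, mirroring how
#' column-wise summary tables are differenced.
#'
#' @param estimates Tidy estimates table.
#' @param intensity Intensity compared (default `"mvpa"`).
#' @param device Reference instrument.
#' @return Data frame: `instrument`, `mean_instrument`, `mean_device`,
#'   `overreporting_min_wk`.
#' @export
overreporting_summary <- function(estimates, intensity = "mvpa",
                                  device = "accelerometer") {
  check_estimates(estimates)
  sub <- estimates[estimates$intensity == intensity, ]
  dev_mean <- mean(sub$minutes_wk[sub$instrument == device], na.rm = TRUE)
  insts <- setdiff(unique(sub$instrument), device)
  out <- do.call(rbind, lapply(insts, function(inst) {
    m <- mean(sub$minutes_wk[sub$instrument == inst], na.rm = TRUE)
    data.frame(instrument = inst, mean_instrument = m, mean_device = dev_mean,
               overreporting_min_wk = m - dev_mean)
  }))
  rownames(out) <- NULL
  out
}
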