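# Independent oracles and fixture builders shared across the suite.

# Naive per-epoch transcription of the nonwear rule: walk the day one
# epoch at a time, tracking the open candidate window, its last zero and
# the current interruption run. Kept deliberately different from the
# package's run-length implementation.
oracle_nonwear_scan <- function(counts, zero_run_min = 60,
                                allow_epochs = 2, allow_cpm = 100) {
  n <- length(counts)
  nonwear <- logical(n)
  start <- NA_integer_; last_zero <- NA_integer_; run <- 0L
  close_window <- function() {
    if (!is.na(start) && last_zero - start + 1L >= zero_run_min) {
      nonwear[start:last_zero] <<- TRUE
    }
  }
  for (i in seq_len(n)) {
    ci <- counts[i]
    if (ci == 0) {
      if (is.na(start)) start <- i
      last_zero <- i
      run <- 0L
    } else if (!is.na(start)) {
      run <- run + 1L
      if (ci > allow_cpm || run > allow_epochs) {
        close_window()
        start <- NA_integer_; last_zero <- NA_integer_; run <- 0L
      }
    }
  }
  close_window()
  !nonwear
}

# Exhaustive window enumeration (small n only): a minute is nonwear iff
# it lies inside some zero-bounded window of sufficient length whose
# interruptions all qualify.
oracle_nonwear_windows <- function(counts, zero_run_min = 60,
                                   allow_epochs = 2, allow_cpm = 100) {
  n <- length(counts)
  nonwear <- logical(n)
  window_ok <- function(i, j) {
    run <- 0L
    for (k in i:j) {
      if (counts[k] == 0) {
        run <- 0L
      } else {
        if (counts[k] > allow_cpm) return(FALSE)
        run <- run + 1L
        if (run > allow_epochs) return(FALSE)
      }
    }
    TRUE
  }
  for (i in seq_len(n)) {
    if (counts[i] != 0) next
    for (j in i:n) {
      if (counts[j] != 0 || j - i + 1L < zero_run_min) next
      if (window_ok(i, j)) nonwear[i:j] <- TRUE
    }
  }
  !nonwear
}

# Block-structured random day: alternating runs of zeros, allowance-band
# counts and clearly-active counts, exercising the interruption logic.
random_epoch_day <- function(n = 1440) {
  x <- integer(0)
  while (length(x) < n) {
    type <- sample(c("zero", "small", "big"), 1, prob = c(0.4, 0.3, 0.3))
    block <- switch(type,
      zero = rep(0L, sample(1:120, 1)),
      small = sample(1:100, sample(1:4, 1), replace = TRUE),
      big = sample(101:8000, sample(1:90, 1), replace = TRUE))
    x <- c(x, block)
  }
  x[seq_len(n)]
}

# Average-rank definition of Spearman's rho, built from first
# principles (positional midranks, then the plain product-moment
# formula) rather than rank()/cor().
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) {
      less <- sum(v < vi)
      ties <- sum(v == vi)
      less + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Squared-difference identity for the concordance correlation:
# rhoc = 1 - E[(x - y)^2] / (s_x^2 + s_y^2 + (xbar - ybar)^2).
oracle_ccc_msd <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  1 - mean((x - y)^2) / (sx2 + sy2 + (mx - my)^2)
}

# Noise- and bias-free generator settings: every instrument should then
# recover the planted truth up to its documented response granularity.
noise_free_params <- function(n = 25, seed = 42, ...) {
  cohort_params(n_participants = n, seed = seed,
                ema_noise_sd = 0, questionnaire_bias_factor = 1,
                questionnaire_noise_cv = 0, sitting_report_factor = 1,
                screen_report_factor = 1, ema_completion_prob = 1,
                accel_compliance_prob = 1, ...)
}

run_small_study <- function(n = 20, seed = 11, ...) {
  run_study(study_config(params = cohort_params(n_participants = n,
                                                seed = seed, ...)))
}
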