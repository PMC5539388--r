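#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average-assigned ranks (midranks
#' for ties); the two-sided p-value uses
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom,
#' accurate at the cohort sizes this battery targets. rho = +/-1 gives
#' p = 0.
#'
#' @param x,y Numeric vectors of equal length, no missing values.
#' @return List with `rho`, `p`, `n`. A constant vector yields missing
#'   values with a warning.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values: form complete-case pairs first")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Holm step-down multiple-testing decisions
#'
#' Applies Holm's sequential Bonferroni procedure to a family of
#' p-values: p-values are ordered ascending and p_(i) is rejected while
#' p_(i) <= alpha / (m - i + 1), stopping at the first failure.
#'
#' @param pvalues Numeric vector in `[0, 1]`; `NA` entries are never
#'   rejected and do not count toward the family size.
#' @param alpha Family-wise error level.
#' @return Logical rejection flags in the original order.
#' @export
holm_adjust <- function(pvalues, alpha = 0.05) {
  stopifnot(is.numeric(pvalues), alpha > 0, alpha < 1)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "holm") <= alpha
  out[!ok] <- FALSE
  out
}

#' Lin's concordance correlation coefficient with asymptotic CI
#'
#' The concordance correlation
#' rhoc = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2),
#' computed with biased (1/n) moment estimators, decomposes into
#' precision (Pearson r) and accuracy (bias correction factor
#' C_b = rhoc / r = 2 / (v + 1/v + u^2), with v = s_x / s_y the scale
#' shift and u = (xbar - ybar) / sqrt(s_x s_y) the location shift).
#' The confidence interval is built on the inverse-hyperbolic-tangent
#' (Fisher z) scale with Lin's asymptotic variance
#' sigma_z^2 = (1/(n-2)) * [ (1 - r^2) rhoc^2 / ((1 - rhoc^2) r^2)
#'   + 4 rhoc^3 (1 - rhoc) u^2 / (r (1 - rhoc^2)^2)
#'   - 2 rhoc^4 u^4 / (r^2 (1 - rhoc^2)^2) ]
#' and back-transformed.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), no missing
#'   values, each with nonzero variance.
#' @param ci_level Confidence level (default 0.95).
#' @return List with `n`, `lcc`, `ci_low`, `ci_high`, `pearson_r`,
#'   `pearson_p` (two-sided t test of r) and `bcf`. Zero variance in
#'   either vector yields missing values with a warning; r = 0 leaves
#'   the bias correction factor undefined (missing).
#' @export
lin_ccc <- function(x, y, ci_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            ci_level > 0, ci_level < 1)
  if (anyNA(x) || anyNA(y)) stop("missing values: form complete-case pairs first")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)          # 1/n convention (Lin 1989)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 || sy2 == 0) {
    warning("zero variance: concordance undefined")
    return(list(n = n, lcc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_, bcf = NA_real_))
  }
  lcc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  bcf <- if (r == 0) NA_real_ else lcc / r
  rp <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
  if (abs(lcc) >= 1 - 1e-14 || r == 0) {
    # degenerate: perfect concordance or undefined accuracy; the
    # asymptotic variance is 0 or undefined respectively
    lo <- hi <- if (abs(lcc) >= 1 - 1e-14) lcc else NA_real_
  } else {
    var_z <- ((1 - r^2) * lcc^2 / ((1 - lcc^2) * r^2) +
              4 * lcc^3 * (1 - lcc) * u^2 / (r * (1 - lcc^2)^2) -
              2 * lcc^4 * u^4 / (r^2 * (1 - lcc^2)^2)) / (n - 2)
    z <- atanh(lcc)
    zq <- stats::qnorm(1 - (1 - ci_level) / 2)
    lo <- tanh(z - zq * sqrt(var_z))
    hi <- tanh(z + zq * sqrt(var_z))
  }
  list(n = n, lcc = lcc, ci_low = lo, ci_high = hi,
       pearson_r = r, pearson_p = rp, bcf = bcf)
}

#' Bland-Altman agreement on log-transformed values
#'
#' Per pair, d = log(x + offset) - log(y + offset) and
#' m = (log(x + offset) + log(y + offset)) / 2; limits of agreement are
#' mean(d) +/- 1.96 sd(d) (sample SD). The additive offset (default 1)
#' accommodates zero minutes; with `offset = 0` all values must be
#' strictly positive.
#'
#' @param x,y Non-negative numeric vectors of equal length (n >= 3).
#' @param offset Additive constant applied before the log.
#' @return List with `mean_diff`, `loa_low`, `loa_high` (log units) and
#'   a data frame `points` of per-pair (mean, diff) plot coordinates.
#' @export
bland_altman_log <- function(x, y, offset = 1) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            offset >= 0)
  if (anyNA(x) || anyNA(y)) stop("missing values: form complete-case pairs first")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (any(x < 0) || any(y < 0)) stop("values must be non-negative")
  if (offset == 0 && (any(x == 0) || any(y == 0))) {
    stop("offset = 0 requires strictly positive values")
  }
  lx <- log(x + offset); ly <- log(y + offset)
  d <- lx - ly
  m <- (lx + ly) / 2
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       points = data.frame(mean = m, diff = d))
}
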