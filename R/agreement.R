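# Inter-reader / interoperation agreement (ICC, Bland-Altman) and cohort
# descriptive comparisons (two-sample t-test, chi-squared).

#' Intraclass correlation coefficient for a rating table
#'
#' Default is ICC(2,1) — two-way random effects, absolute agreement,
#' single measurement — computed from the two-way ANOVA mean squares:
#'
#'   ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
#'
#' with MSR the between-subject, MSC the between-rater and MSE the
#' residual mean square over n subjects and k raters. `type = "ICC3"`
#' gives the two-way mixed, consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)`. Agreement above 0.75 is
#' conventionally read as good reliability.
#'
#' @param table numeric matrix or data.frame: rows = subjects (>= 3),
#'   columns = raters/occasions (>= 2), no missing cells.
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return Scalar ICC (<= 1); zero between-subject variance returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
icc_agreement <- function(table, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  m <- as.matrix(table)
  if (any(is.na(m))) stop("rating table must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)           # between subjects
  ssc <- n * sum((col_m - grand)^2)           # between raters
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse && msr == 0)
    return(structure(0, degenerate = TRUE))
  icc <- if (type == "ICC2")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  if (!is.finite(icc)) structure(0, degenerate = TRUE) else icc
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`: bias is their mean, the 95% limits of
#' agreement are `bias +/- 1.96 SD(d)` (sample SD, n-1), and `p_bias` is
#' the two-sided paired t-test of the differences against zero.
#'
#' @param x,y paired measurements, equal length >= 3.
#' @return A `bland_altman` list: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `outside_count` (points beyond the limits), `n`, `p_bias`,
#'   `differences`, `means`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sdd
  p <- if (sdd <= .Machine$double.eps^0.5 * max(1, abs(bias))) {
    if (abs(bias) <= .Machine$double.eps^0.5) 1 else 0
  } else stats::t.test(d)$p.value
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 sd_diff = sdd,
                 outside_count = sum(d < loa[1] | d > loa[2]),
                 n = length(d), p_bias = p,
                 differences = d, means = (x + y) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4f [LoA %.4f, %.4f], %d/%d outside, p_bias %.3g\n",
              x$bias, x$loa_low, x$loa_high, x$outside_count, x$n, x$p_bias))
  invisible(x)
}

#' Two-group descriptive comparison
#'
#' Continuous variables are compared with a two-sample t-test (two-sided);
#' categorical variables with a chi-squared test on the contingency table
#' (no continuity correction, so the statistic equals `sum((O-E)^2 / E)`).
#'
#' @param group_a,group_b vectors of the variable in the two groups
#'   (numeric for continuous; anything coercible to factor for
#'   categorical).
#' @param variable_type `"continuous"` or `"categorical"`.
#' @param var_equal for continuous: pool variances (the classical
#'   two-sample t-test, default); `FALSE` gives the Welch form.
#' @return List: `statistic`, `p`, `method`.
#' @export
cohort_compare <- function(group_a, group_b,
                           variable_type = c("continuous", "categorical"),
                           var_equal = TRUE) {
  variable_type <- match.arg(variable_type)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (variable_type == "continuous") {
    if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
      stop("both groups have zero variance; a t-test is undefined ",
           "(compare the constants directly)")
    tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         method = "two-sample t-test")
  } else {
    lev <- union(unique(group_a), unique(group_b))
    tab <- rbind(table(factor(group_a, levels = lev)),
                 table(factor(group_b, levels = lev)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chi-squared test")
  }
}
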