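#' Paired t-test for systematic bias (learning effect)
#'
#' Tests whether the mean test--retest difference differs from zero.
#' Differences are taken as earlier minus later (`x - y`), so a test scored
#' in time shows a positive bias when performance improves across
#' occasions and a hit count shows a negative one. If all differences are
#' zero the test is degenerate and `p = 1` is returned with a flag; zero
#' variance around a nonzero bias is an error.
#'
#' @param pair a [paired_comparison()].
#' @return a `bias_test` with `bias`, `t_stat`, `df`, `p_raw`,
#'   `p_adjusted` (`NA` until a multiplicity correction assigns it) and
#'   `degenerate` flag.
#' @export
paired_bias_test <- function(pair) {
  stopifnot(inherits(pair, "paired_comparison"))
  d <- pair$x - pair$y
  n <- pair$n
  if (n < 2L) stop("paired t-test needs n >= 2")
  bias <- mean(d)
  if (stats::sd(d) == 0) {
    if (bias != 0) {
      stop("degenerate variance: identical nonzero differences; no test possible")
    }
    return(structure(list(bias = 0, t_stat = 0, df = n - 1L,
                          p_raw = 1, p_adjusted = NA_real_,
                          n = n, degenerate = TRUE, label = pair$label),
                     class = "bias_test"))
  }
  tt <- stats::t.test(pair$x, pair$y, paired = TRUE)
  structure(list(bias = bias,
                 t_stat = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_adjusted = NA_real_,
                 n = n, degenerate = FALSE, label = pair$label),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("Systematic bias '%s': %.4g (t = %.3f, df = %d, p = %.4g%s)\n",
              x$label, x$bias, x$t_stat, x$df, x$p_raw,
              if (is.na(x$p_adjusted)) "" else
                sprintf(", adj. p = %.4g", x$p_adjusted)))
  invisible(x)
}

#' Multiplicity adjustment of p-values
#'
#' Thin wrapper around [stats::p.adjust()] restricted to the corrections
#' used in reliability reporting: Holm's step-down (default), plain
#' Bonferroni, or none.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"holm"`, `"bonferroni"` or `"none"`.
#' @return adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Per-test Bonferroni significance threshold
#'
#' The family-wise level divided by the family size, e.g. 0.05 / 25 =
#' 0.002 for a family of 25 reliability comparisons.
#'
#' @param alpha family-wise significance level.
#' @param m family size (number of tests).
#' @return per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Mean absolute error of a test--retest pair
#'
#' \eqn{MAE = \frac{1}{n}\sum_i |x_i - y_i|}, in score units.
#'
#' @param pair a [paired_comparison()].
#' @return non-negative MAE.
#' @export
mae <- function(pair) {
  stopifnot(inherits(pair, "paired_comparison"))
  mean(abs(pair$x - pair$y))
}

#' Mean absolute percentage error of a test--retest pair
#'
#' \eqn{MAPE = \frac{1}{n}\sum_i |(x_i - y_i)/x_i| \times 100}, with the
#' chronologically earlier measurement `x` as the reference.
#'
#' @param pair a [paired_comparison()].
#' @return MAPE in percent.
#' @export
mape <- function(pair) {
  stopifnot(inherits(pair, "paired_comparison"))
  if (any(pair$x == 0)) {
    bad <- pair$subjects[pair$x == 0]
    stop("MAPE undefined: zero reference value for subject(s) ",
         paste(bad, collapse = ", "))
  }
  mean(abs((pair$x - pair$y) / pair$x)) * 100
}

#' Bland--Altman agreement analysis
#'
#' Computes the mean difference (bias), the limits of agreement
#' \eqn{bias \pm 1.96\,SD_d} and 95\% confidence intervals for all three
#' lines: a t-interval for the bias and Bland & Altman's approximation
#' \eqn{Var(LoA) = SD_d^2 (1/n + z^2 / (2(n-1)))} for each limit.
#'
#' @param pair a [paired_comparison()].
#' @param loa_factor multiplier for the limits of agreement (1.96 for the
#'   95\% range).
#' @param conf.level confidence level for the interval estimates.
#' @return a `bland_altman` object; `as.data.frame()` yields the
#'   per-subject (mean, difference) points for plotting.
#' @export
bland_altman <- function(pair, loa_factor = 1.96, conf.level = 0.95) {
  stopifnot(inherits(pair, "paired_comparison"))
  d <- pair$x - pair$y
  n <- pair$n
  if (n < 2L) stop("Bland-Altman analysis needs n >= 2")
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * loa_factor * sd_d
  alpha <- 1 - conf.level
  tq <- stats::qt(1 - alpha / 2, df = n - 1L)
  ci_bias <- bias + c(-1, 1) * tq * sd_d / sqrt(n)
  se_loa <- if (n >= 3L) {
    sqrt(sd_d^2 * (1 / n + loa_factor^2 / (2 * (n - 1))))
  } else NA_real_
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = loa[1L], loa_high = loa[2L],
                 ci_bias = ci_bias,
                 ci_loa_low = loa[1L] + c(-1, 1) * tq * se_loa,
                 ci_loa_high = loa[2L] + c(-1, 1) * tq * se_loa,
                 loa_factor = loa_factor, conf.level = conf.level,
                 n = n, label = pair$label,
                 means = (pair$x + pair$y) / 2, diffs = d,
                 subjects = pair$subjects),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman '%s' (n = %d):\n", x$label, x$n))
  cat(sprintf("  bias %.4g [%.4g, %.4g]\n", x$bias, x$ci_bias[1L], x$ci_bias[2L]))
  cat(sprintf("  LoA  %.4g to %.4g\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
as.data.frame.bland_altman <- function(x, ...) {
  data.frame(subject = x$subjects, mean = x$means, diff = x$diffs)
}

#' Shapiro--Wilk normality check
#'
#' Applied to paired differences before bias testing and to raw scores for
#' descriptive reporting. Delegates to [stats::shapiro.test()].
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk supports 3 <= n <= 5000 (got ", n, ")")
  }
  if (stats::sd(values) == 0) stop("normality check degenerate: constant values")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}
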