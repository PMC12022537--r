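#' Two-way mean-square decomposition of a test--retest pair
#'
#' Decomposes the n-subjects-by-2-occasions score matrix into the mean
#' squares underlying the intraclass correlation: rows (subjects), columns
#' (occasions) and residual. SS_total = SS_rows + SS_cols + SS_error.
#'
#' @param pair a [paired_comparison()], or a numeric vector `x` when `y`
#'   is also supplied.
#' @param y optional second score vector when `pair` is a plain vector.
#' @return an `anova_decomp` object with elements `msr`, `msc`, `mse`,
#'   the sums of squares, `n`, `k` and degrees of freedom.
#' @examples
#' d <- ms_decomposition(c(1, 2, 3), c(2, 3, 4))
#' d$msc  # n * (mean shift)^2 / (k - 1)
#' @export
ms_decomposition <- function(pair, y = NULL) {
  if (inherits(pair, "paired_comparison")) {
    x <- pair$x; y <- pair$y
  } else {
    x <- as.numeric(pair)
    if (is.null(y)) stop("supply a paired_comparison or both x and y")
  }
  n <- length(x)
  if (n < 2L) stop("mean-square decomposition needs n >= 2 subjects")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("scores must be finite")
  m <- cbind(x, y)
  k <- 2L
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  df_rows <- n - 1L
  df_cols <- k - 1L
  df_error <- (n - 1L) * (k - 1L)
  structure(list(msr = ss_rows / df_rows,
                 msc = ss_cols / df_cols,
                 mse = max(ss_error, 0) / df_error,
                 ss_rows = ss_rows, ss_cols = ss_cols,
                 ss_error = ss_error, ss_total = ss_total,
                 n = n, k = k,
                 df_rows = df_rows, df_cols = df_cols, df_error = df_error),
            class = "anova_decomp")
}

#' @export
print.anova_decomp <- function(x, ...) {
  cat(sprintf("Two-way mean squares (n = %d, k = %d):\n", x$n, x$k))
  cat(sprintf("  MSR (subjects)  %.6g on %d df\n", x$msr, x$df_rows))
  cat(sprintf("  MSC (occasions) %.6g on %d df\n", x$msc, x$df_cols))
  cat(sprintf("  MSE (residual)  %.6g on %d df\n", x$mse, x$df_error))
  invisible(x)
}

#' Absolute-agreement intraclass correlation
#'
#' Computes the two-way, single-measure, absolute-agreement intraclass
#' correlation ICC(A,1) from a mean-square decomposition:
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}}
#' with an F-based 95\% confidence interval after McGraw & Wong's
#' construction for Case 2A. The `"paper"` variant evaluates the reduced
#' expression \eqn{(MSR - MSE) / (MSR + (MSC - MSE)/n)}, which omits the
#' \eqn{(k-1)MSE} term of the standard form; it is provided for
#' comparability with reports that print that expression and carries no
#' analytic confidence interval.
#'
#' @param decomp an [ms_decomposition()] result or a
#'   [paired_comparison()] (decomposed internally).
#' @param variant `"standard"` for ICC(A,1) (default) or `"paper"` for the
#'   reduced expression.
#' @param conf.level confidence level for the interval (standard variant).
#' @return an `icc_result` with `estimate`, `ci_low`, `ci_high`, `variant`
#'   and interpretation `band`.
#' @references McGraw, K.O. & Wong, S.P. (1996). Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods 1(1).
#' @export
icc_agreement <- function(decomp, variant = c("standard", "paper"),
                          conf.level = 0.95) {
  variant <- match.arg(variant)
  if (inherits(decomp, "paired_comparison")) decomp <- ms_decomposition(decomp)
  stopifnot(inherits(decomp, "anova_decomp"))
  msr <- decomp$msr; msc <- decomp$msc; mse <- decomp$mse
  n <- decomp$n; k <- decomp$k

  if (variant == "paper") {
    denom <- msr + (msc - mse) / n
    if (abs(denom) < .Machine$double.eps * max(1, msr)) {
      stop("ICC undefined: zero denominator")
    }
    est <- (msr - mse) / denom
    ci <- c(NA_real_, NA_real_)
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (abs(denom) < .Machine$double.eps * max(1, msr)) {
      stop("ICC undefined: zero denominator")
    }
    est <- (msr - mse) / denom
    ci <- icc_a1_ci(msr, msc, mse, n, k, est, conf.level)
  }
  if (est < 0) {
    warning("negative ICC estimate (", signif(est, 3),
            "); SEM/MDC are undefined unless clamped to 0 by the caller")
  }
  structure(list(estimate = est, ci_low = ci[1L], ci_high = ci[2L],
                 variant = variant, band = icc_band(max(min(est, 1), -1)),
                 conf.level = conf.level,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

# F-based CI for ICC(A,1), McGraw & Wong (1996) Case 2A.
icc_a1_ci <- function(msr, msc, mse, n, k, icc, conf.level) {
  alpha <- 1 - conf.level
  if (mse <= 0) {
    # degenerate: no residual variance; interval collapses at the estimate
    return(c(icc, icc))
  }
  if (icc >= 1) return(c(1, 1))
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  fj <- msc / mse
  v <- (a * fj + b)^2 /
    ((a^2 * fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  c(lo, hi)
}

#' @export
print.icc_result <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (%.0f%% CI %.2f-%.2f)", 100 * x$conf.level, x$ci_low, x$ci_high)
  cat(sprintf("ICC[%s] = %.3f%s, %s reliability (n = %d)\n",
              x$variant, x$estimate, ci, x$band, x$n))
  invisible(x)
}

#' Standard error of measurement
#'
#' \eqn{SEM = SD \sqrt{1 - ICC}}. The SD basis is chosen by the caller;
#' the reliability tables default to the standard deviation of the paired
#' differences.
#'
#' @param sd_basis non-negative standard deviation in score units.
#' @param icc reliability estimate in \[0, 1\]; negative estimates must be
#'   clamped or rejected explicitly by the caller.
#' @return SEM in score units.
#' @export
sem_from <- function(sd_basis, icc) {
  if (any(icc < 0 | icc > 1)) stop("icc must lie in [0, 1]")
  if (any(sd_basis < 0)) stop("sd_basis must be >= 0")
  sd_basis * sqrt(1 - icc)
}

#' Minimal detectable change
#'
#' \eqn{MDC = SEM \times 1.96 \times \sqrt{2}}: the smallest change
#' exceeding measurement error with 95\% confidence.
#'
#' @param sem non-negative standard error of measurement.
#' @return MDC in score units.
#' @examples
#' round(mdc_from(0.91), 2)
#' @export
mdc_from <- function(sem) {
  if (any(sem < 0)) stop("sem must be >= 0")
  sem * 1.96 * sqrt(2)
}

#' Qualitative reliability band for an ICC estimate
#'
#' Koo & Li interpretation: below 0.50 poor, 0.50 to below 0.75 moderate,
#' 0.75 to below 0.90 good, 0.90 and above excellent.
#'
#' @param estimate ICC estimate in \[-1, 1\].
#' @return character: `"poor"`, `"moderate"`, `"good"` or `"excellent"`.
#' @export
icc_band <- function(estimate) {
  if (any(estimate < -1 | estimate > 1)) stop("estimate must lie in [-1, 1]")
  vapply(estimate, function(e) {
    if (e < 0.50) "poor"
    else if (e < 0.75) "moderate"
    else if (e < 0.90) "good"
    else "excellent"
  }, character(1L))
}
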