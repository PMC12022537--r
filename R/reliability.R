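#' Reliability table for one comparison mode
#'
#' Builds the standard test--retest reliability report: one row per test
#' per comparison (days 1..D for intraday; 1_2 .. (D-1)_D then 1_D for
#' interday), each carrying means and SDs of both occasions, the
#' absolute-agreement ICC with its confidence interval and qualitative
#' band, SEM and MDC, the systematic bias with raw and
#' multiplicity-adjusted p-values, and the random-error magnitudes MAE and
#' MAPE. The multiplicity family is all rows of the requested mode, so a
#' 5-test 5-day intraday table adjusts over 25 comparisons.
#'
#' @param ds a [trial_data()] dataset.
#' @param mode `"intraday"` or `"interday"`.
#' @param alpha family-wise significance level.
#' @param multiplicity `"holm"`, `"bonferroni"` or `"none"`.
#' @param icc_variant `"standard"` (ICC(A,1)) or `"paper"` (see
#'   [icc_agreement()]).
#' @param sem_basis SD entering the SEM: `"diff"` for the SD of paired
#'   differences (default) or `"pooled"` for the SD of all scores in the
#'   pair. Negative ICC estimates are clamped to 0 for the SEM.
#' @param conf.level confidence level for ICC intervals.
#' @return data.frame of reliability rows (unrounded; see
#'   [format_reliability()] for display formatting).
#' @export
reliability_table <- function(ds, mode = c("intraday", "interday"),
                              alpha = 0.05,
                              multiplicity = c("holm", "bonferroni", "none"),
                              icc_variant = c("standard", "paper"),
                              sem_basis = c("diff", "pooled"),
                              conf.level = 0.95) {
  stopifnot(inherits(ds, "trial_data"))
  mode <- match.arg(mode)
  multiplicity <- match.arg(multiplicity)
  icc_variant <- match.arg(icc_variant)
  sem_basis <- match.arg(sem_basis)

  tests <- unique(ds$test)
  rows <- list()
  for (test in tests) {
    for (pair in make_pairs(ds, test, mode = mode)) {
      icc <- icc_agreement(ms_decomposition(pair), variant = icc_variant,
                           conf.level = conf.level)
      sd_basis <- switch(sem_basis,
                         diff = stats::sd(pair$x - pair$y),
                         pooled = stats::sd(c(pair$x, pair$y)))
      sem <- sem_from(sd_basis, max(min(icc$estimate, 1), 0))
      bt <- paired_bias_test(pair)
      rows[[length(rows) + 1L]] <- data.frame(
        test = test,
        comparison = sub(paste0("^", test, " "), "", pair$label, fixed = FALSE),
        label = pair$label, kind = pair$kind, n = pair$n,
        mean_1 = mean(pair$x), sd_1 = stats::sd(pair$x),
        mean_2 = mean(pair$y), sd_2 = stats::sd(pair$y),
        icc = icc$estimate, icc_low = icc$ci_low, icc_high = icc$ci_high,
        icc_band = icc$band,
        sem = sem, mdc = mdc_from(sem),
        bias = bt$bias, t_stat = bt$t_stat, df = bt$df, p_raw = bt$p_raw,
        p_adjusted = NA_real_, significant = NA,
        mae = mae(pair), mape = mape(pair),
        units = pair$units)
    }
  }
  if (length(rows) == 0L) {
    warning("empty dataset: no comparisons")
    return(data.frame())
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adjusted <- adjust_pvalues(tab$p_raw, method = multiplicity)
  tab$significant <- tab$p_adjusted < alpha
  attr(tab, "mode") <- mode
  attr(tab, "alpha") <- alpha
  attr(tab, "multiplicity") <- multiplicity
  attr(tab, "family_size") <- nrow(tab)
  tab
}

#' Format a reliability table for display
#'
#' Rounds to two decimals and renders tiny p-values as `"< 0.001"`,
#' mirroring conventional reliability reporting. All arithmetic stays in
#' the unrounded table; this is a formatting layer only.
#'
#' @param tab a [reliability_table()] result.
#' @return data.frame of character columns ready for printing.
#' @export
format_reliability <- function(tab) {
  f2 <- function(v) formatC(v, format = "f", digits = 2)
  data.frame(
    Test = tab$label,
    `Mean1_SD1` = paste0(f2(tab$mean_1), " ± ", f2(tab$sd_1)),
    `Mean2_SD2` = paste0(f2(tab$mean_2), " ± ", f2(tab$sd_2)),
    ICC_CI = ifelse(is.na(tab$icc_low), f2(tab$icc),
                    sprintf("%s (%s-%s)", f2(tab$icc), f2(tab$icc_low),
                            f2(tab$icc_high))),
    SEM = f2(tab$sem), MDC = f2(tab$mdc),
    Bias_p = sprintf("%s (%s)", f2(tab$bias), format_p(tab$p_adjusted)),
    MAE = f2(tab$mae), MAPE = f2(tab$mape),
    check.names = FALSE)
}

#' Display convention for p-values
#'
#' @param p numeric p-values.
#' @param digits rounding digits for displayable values.
#' @return character vector, `"< 0.001"` below that threshold.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(p < 0.001, "< 0.001", formatC(round(p, digits), format = "g"))
}

#' Habituation-aware reliability analysis
#'
#' The main fitting function: runs the full pipeline on a long-format
#' repeated-measures dataset. For every test it computes the intraday and
#' interday reliability tables ([reliability_table()]), the overall
#' learning curve, the habituation decision (when does systematic bias
#' become nonsignificant while random error stays stable,
#' [detect_stabilization()]) and, when at least two groups are present,
#' the mixed group-by-time ANOVA and first-to-last-day change-score
#' comparison.
#'
#' @param data a [trial_data()] dataset, or a data.frame coercible by
#'   [trial_data()].
#' @param alpha family-wise significance level.
#' @param multiplicity p-value correction (`"holm"`, `"bonferroni"`,
#'   `"none"`).
#' @param icc_variant `"standard"` or `"paper"` (see [icc_agreement()]).
#' @param sem_basis `"diff"` or `"pooled"` (see [reliability_table()]).
#' @param mape_tolerance maximum consecutive-day MAPE change (percentage
#'   points) counted as stable random error.
#' @param group_analysis run the group-effects layer (needs >= 2 groups).
#' @param conf.level confidence level for interval estimates.
#' @return a `reliability_fit` with components `intraday`, `interday`,
#'   `curves`, `decisions`, `recommendation`, `group_effects`,
#'   `change_scores`, the analysis `config` and the input `data`.
#' @examples
#' ds <- simulate_cohort(cohort_preset(), seed = 1)
#' fit <- reliability(ds)
#' fit
#' @export
reliability <- function(data, alpha = 0.05,
                        multiplicity = c("holm", "bonferroni", "none"),
                        icc_variant = c("standard", "paper"),
                        sem_basis = c("diff", "pooled"),
                        mape_tolerance = 5,
                        group_analysis = TRUE,
                        conf.level = 0.95) {
  if (!inherits(data, "trial_data")) data <- trial_data(data)
  multiplicity <- match.arg(multiplicity)
  icc_variant <- match.arg(icc_variant)
  sem_basis <- match.arg(sem_basis)
  stopifnot(alpha > 0, alpha < 1, mape_tolerance >= 0)

  intraday <- reliability_table(data, "intraday", alpha = alpha,
                                multiplicity = multiplicity,
                                icc_variant = icc_variant,
                                sem_basis = sem_basis,
                                conf.level = conf.level)
  interday <- reliability_table(data, "interday", alpha = alpha,
                                multiplicity = multiplicity,
                                icc_variant = icc_variant,
                                sem_basis = sem_basis,
                                conf.level = conf.level)

  tests <- unique(data$test)
  curves <- lapply(stats::setNames(tests, tests), function(test) {
    learning_curve(data, test, group = "overall",
                   multiplicity = multiplicity)
  })
  decisions <- lapply(curves, detect_stabilization, alpha = alpha,
                      mape_tolerance = mape_tolerance)
  recommendation <- recommend_sessions(decisions)

  ge <- NULL; cs <- NULL
  if (group_analysis && length(unique(data$group)) >= 2L) {
    ge <- lapply(stats::setNames(tests, tests),
                 function(test) rm_anova(data, test))
    cs <- lapply(stats::setNames(tests, tests),
                 function(test) change_scores(data, test))
  }

  structure(list(intraday = intraday, interday = interday,
                 curves = curves, decisions = decisions,
                 recommendation = recommendation,
                 group_effects = ge, change_scores = cs,
                 config = list(alpha = alpha, multiplicity = multiplicity,
                               icc_variant = icc_variant,
                               sem_basis = sem_basis,
                               mape_tolerance = mape_tolerance,
                               conf.level = conf.level),
                 data = data),
            class = "reliability_fit")
}

#' @export
print.reliability_fit <- function(x, ...) {
  ds <- x$data
  cat(sprintf("Habituation-aware reliability analysis\n"))
  cat(sprintf("  %d subjects, %d group(s), %d test(s); alpha = %g (%s over %d %s + %d %s comparisons)\n",
              length(unique(ds$subject)), length(unique(ds$group)),
              length(unique(ds$test)), x$config$alpha,
              x$config$multiplicity,
              nrow(x$intraday), "intraday", nrow(x$interday), "interday"))
  cat("Stabilization day per test (overall):\n")
  rec <- x$recommendation
  for (i in seq_len(nrow(rec))) {
    cat(sprintf("  %-18s %s\n", rec$test[i],
                ifelse(is.na(rec$stabilization_day[i]), "not reached",
                       paste("day", rec$stabilization_day[i]))))
  }
  cat(sprintf("Overall recommended familiarization sessions: %s\n",
              attr(rec, "overall")))
  invisible(x)
}

#' @export
summary.reliability_fit <- function(object, ...) {
  structure(list(fit = object,
                 intraday = format_reliability(object$intraday),
                 interday = format_reliability(object$interday)),
            class = "summary.reliability_fit")
}

#' @export
print.summary.reliability_fit <- function(x, ...) {
  print(x$fit)
  cat("\nIntraday reliability:\n")
  print(x$intraday, row.names = FALSE)
  cat("\nInterday reliability:\n")
  print(x$interday, row.names = FALSE)
  if (!is.null(x$fit$group_effects)) {
    cat("\nGroup x time effects:\n")
    for (ge in x$fit$group_effects) print(ge)
  }
  invisible(x)
}

#' Plot learning curves of a reliability fit
#'
#' One panel per test: day means connected across sessions with vertical
#' bars showing the standard error of the mean.
#'
#' @param x a [reliability()] fit.
#' @param tests subset of test labels (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.reliability_fit <- function(x, tests = names(x$curves), ...) {
  n <- length(tests)
  old <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2L)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (test in tests) {
    cu <- x$curves[[test]]
    d <- cu$days
    ylim <- range(d$mean - d$sem_of_mean, d$mean + d$sem_of_mean)
    graphics::plot(d$day, d$mean, type = "b", pch = 19,
                   xlab = "Day", ylab = "Mean score", main = test,
                   ylim = ylim, ...)
    graphics::arrows(d$day, d$mean - d$sem_of_mean,
                     d$day, d$mean + d$sem_of_mean,
                     angle = 90, code = 3, length = 0.04)
    sd_day <- x$decisions[[test]]$stabilization_day
    if (!is.na(sd_day)) graphics::abline(v = sd_day, lty = 3)
  }
  invisible(x)
}
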