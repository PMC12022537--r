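#' Build a learning curve for one test
#'
#' Assembles the session-by-session picture used to judge habituation:
#' day-level means, SDs and standard errors of the mean, plus the
#' consecutive-day systematic biases (paired t-tests, multiplicity
#' adjusted within the curve) and random-error (MAPE) series.
#'
#' @param ds a [trial_data()] dataset.
#' @param test test label.
#' @param group a group label, or `"overall"` for the pooled cohort.
#' @param multiplicity correction applied across the curve's
#'   consecutive-day bias tests (see [adjust_pvalues()]).
#' @return a `learning_curve` with `days` (data.frame day, mean, sd,
#'   sem_of_mean, n) and `comparisons` (data.frame label, day_from,
#'   day_to, n, bias, p_raw, p_adjusted, mape, mdc).
#' @export
learning_curve <- function(ds, test, group = "overall",
                           multiplicity = c("holm", "bonferroni", "none")) {
  stopifnot(inherits(ds, "trial_data"))
  multiplicity <- match.arg(multiplicity)
  if (!identical(group, "overall")) {
    keep <- ds$group == group
    if (!any(keep)) stop("no observations for group '", group, "'")
    ds <- structure(ds[keep, , drop = FALSE],
                    higher_is_better = attr(ds, "higher_is_better"),
                    units = attr(ds, "units"),
                    n_dropped = attr(ds, "n_dropped"),
                    class = class(ds))
  }
  dm <- day_means(ds, test)
  if (length(unique(dm$day)) < 2L) stop("learning curve needs >= 2 days")
  days <- do.call(rbind, lapply(split(dm, dm$day), function(d) {
    data.frame(day = d$day[1L], mean = mean(d$score),
               sd = stats::sd(d$score),
               sem_of_mean = stats::sd(d$score) / sqrt(nrow(d)),
               n = nrow(d))
  }))
  rownames(days) <- NULL

  pairs <- make_pairs(ds, test, mode = "interday")
  pairs <- Filter(function(p) p$kind == "interday", pairs)
  cmp <- do.call(rbind, lapply(pairs, function(p) {
    bt <- paired_bias_test(p)
    icc <- icc_agreement(ms_decomposition(p))
    sem <- sem_from(stats::sd(p$x - p$y), max(icc$estimate, 0))
    from_to <- as.integer(strsplit(sub(".* ", "", p$label), "_")[[1L]])
    data.frame(label = p$label, day_from = from_to[1L], day_to = from_to[2L],
               n = p$n, bias = bt$bias, p_raw = bt$p_raw,
               p_adjusted = NA_real_, mape = mape(p), mdc = mdc_from(sem))
  }))
  cmp <- cmp[order(cmp$day_from), , drop = FALSE]
  rownames(cmp) <- NULL
  cmp$p_adjusted <- adjust_pvalues(cmp$p_raw, method = multiplicity)
  structure(list(test = test, group = group, days = days,
                 comparisons = cmp, multiplicity = multiplicity),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve: %s (%s)\n", x$test, x$group))
  print(cbind(x$days[c("day", "mean", "sd", "n")]), row.names = FALSE)
  cat("Consecutive-day comparisons:\n")
  print(x$comparisons[c("label", "bias", "p_adjusted", "mape")],
        row.names = FALSE)
  invisible(x)
}

#' Decide when performance has habituated
#'
#' A testing protocol counts as habituated once the systematic bias is
#' nonsignificant and the random error has stabilized. For each
#' consecutive-day comparison (d, d+1): `bias_ok` iff the adjusted p-value
#' is >= `alpha`; `random_error_ok` iff the absolute change in MAPE from
#' the previous comparison is <= `mape_tolerance` (the first comparison is
#' vacuously stable). The stabilization day is the earliest day d such
#' that both criteria hold for every comparison from (d, d+1) onwards —
#' requiring all later comparisons to stay stable guards against
#' non-monotone random-error sequences.
#'
#' Nonsignificance is not evidence of irrelevance: the decision trace
#' carries each bias point estimate next to the comparison's minimal
#' detectable change so residual learning below the detection limit stays
#' visible.
#'
#' @param curve a [learning_curve()].
#' @param alpha significance level applied to adjusted bias p-values.
#' @param mape_tolerance maximum absolute change in consecutive-day MAPE
#'   (percentage points) still counted as stable.
#' @return a `habituation_decision` with `stabilization_day` (integer or
#'   `NA` if never stable) and the per-comparison criterion trace.
#' @export
detect_stabilization <- function(curve, alpha = 0.05, mape_tolerance = 5) {
  stopifnot(inherits(curve, "learning_curve"), alpha > 0, alpha < 1,
            mape_tolerance >= 0)
  cmp <- curve$comparisons
  if (nrow(cmp) < 1L) stop("curve has no consecutive-day comparisons")
  if (any(is.na(cmp$p_adjusted))) stop("curve is missing adjusted p-values")
  bias_ok <- cmp$p_adjusted >= alpha
  dmape <- c(0, abs(diff(cmp$mape)))
  random_error_ok <- dmape <= mape_tolerance
  ok <- bias_ok & random_error_ok
  stable_from <- which(rev(cumprod(rev(ok))) == 1)
  day <- if (length(stable_from) == 0L) NA_integer_ else
    cmp$day_from[stable_from[1L]]
  trace <- data.frame(label = cmp$label, day_from = cmp$day_from,
                      day_to = cmp$day_to, bias = cmp$bias,
                      p_adjusted = cmp$p_adjusted, mape = cmp$mape,
                      mdc = cmp$mdc,
                      bias_ok = bias_ok, random_error_ok = random_error_ok)
  structure(list(test = curve$test, group = curve$group,
                 stabilization_day = day, trace = trace,
                 alpha_used = alpha, mape_tolerance = mape_tolerance),
            class = "habituation_decision")
}

#' @export
print.habituation_decision <- function(x, ...) {
  day <- if (is.na(x$stabilization_day)) "not reached within the observed days"
  else paste("day", x$stabilization_day)
  cat(sprintf("Habituation decision for %s (%s): %s\n", x$test, x$group, day))
  print(x$trace[c("label", "bias", "p_adjusted", "mape", "mdc",
                  "bias_ok", "random_error_ok")], row.names = FALSE)
  invisible(x)
}

#' Recommend familiarization sessions
#'
#' Summarizes habituation decisions into a recommended number of
#' familiarization sessions per test (the stabilization day) and an
#' overall recommendation: the maximum across tests, or `"undetermined"`
#' if any test never stabilized within the observed days.
#'
#' @param decisions list of [detect_stabilization()] results.
#' @return data.frame of per-test/group recommendations with the overall
#'   recommendation in `attr(, "overall")`.
#' @export
recommend_sessions <- function(decisions) {
  if (inherits(decisions, "habituation_decision")) decisions <- list(decisions)
  stopifnot(length(decisions) >= 1L)
  tab <- do.call(rbind, lapply(decisions, function(d) {
    stopifnot(inherits(d, "habituation_decision"))
    data.frame(test = d$test, group = d$group,
               stabilization_day = d$stabilization_day,
               recommended_sessions = d$stabilization_day)
  }))
  overall <- if (any(is.na(tab$stabilization_day))) "undetermined"
  else max(tab$stabilization_day)
  structure(tab, overall = overall)
}
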