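#' Mixed between-group / within-time repeated-measures ANOVA
#'
#' Fits the group (between-subjects) by day (within-subjects) ANOVA on the
#' per-subject day means of one test, with subjects nested in groups.
#' Sums of squares come from the classical stratified decomposition
#' ([stats::aov()] with an `Error(subject)` term); partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each effect's stratum.
#' When the within factor has more than two levels, Greenhouse--Geisser
#' corrected p-values (epsilon from the pooled within-group covariance
#' matrix) are reported alongside the uncorrected ones.
#'
#' @param ds a [trial_data()] dataset with >= 2 groups.
#' @param test test label.
#' @return an `rm_anova` object: `effects` data.frame (one row each for
#'   group, day and group:day with SS, df, F, p, `p_gg`, partial eta
#'   squared and its interpretation band), `epsilon_gg`, and the wide
#'   day-mean matrix used.
#' @export
rm_anova <- function(ds, test) {
  stopifnot(inherits(ds, "trial_data"))
  dm <- day_means(ds, test)
  days <- sort(unique(dm$day))
  if (length(days) < 2L) stop("repeated-measures ANOVA needs >= 2 days")

  # complete day-mean matrix per retained subject
  wide <- stats::reshape(dm[c("subject", "group", "day", "score")],
                         idvar = c("subject", "group"), timevar = "day",
                         direction = "wide")
  day_cols <- paste0("score.", days)
  wide <- wide[stats::complete.cases(wide[day_cols]), , drop = FALSE]
  gsize <- table(wide$group)
  if (length(gsize) < 2L) stop("repeated-measures ANOVA needs >= 2 groups")
  if (any(gsize < 2L)) {
    stop("group(s) with < 2 complete subjects: ",
         paste(names(gsize)[gsize < 2L], collapse = ", "))
  }

  long <- stats::reshape(wide, direction = "long", idvar = "subject",
                         varying = day_cols, v.names = "score",
                         timevar = "day", times = days)
  long$subject <- factor(long$subject)
  long$group <- factor(long$group)
  long$dayf <- factor(long$day)

  fit <- stats::aov(score ~ group * dayf + Error(subject), data = long)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1L]])
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))

  pull <- function(tab, rn, effect) {
    i <- match(effect, rn)
    err <- match("Residuals", rn)
    ss_eff <- tab[i, "Sum Sq"]; ss_err <- tab[err, "Sum Sq"]
    data.frame(effect = effect,
               ss = ss_eff, df = tab[i, "Df"],
               ss_error = ss_err, df_error = tab[err, "Df"],
               F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
               partial_eta_sq = ss_eff / (ss_eff + ss_err))
  }
  eff <- rbind(pull(between, rn_b, "group"),
               pull(within, rn_w, "dayf"),
               pull(within, rn_w, "group:dayf"))
  eff$effect <- c("group", "day", "group:day")

  eps <- NA_real_
  eff$p_gg <- eff$p
  if (length(days) > 2L) {
    eps <- gg_epsilon(as.matrix(wide[day_cols]), wide$group)
    for (i in 2:3) {
      eff$p_gg[i] <- stats::pf(eff$F[i], eps * eff$df[i],
                               eps * eff$df_error[i], lower.tail = FALSE)
    }
  }
  eff$eta_band <- eta_sq_band(eff$partial_eta_sq)
  rownames(eff) <- NULL

  structure(list(effects = eff, epsilon_gg = eps,
                 design = list(n_per_group = as.vector(gsize),
                               group_labels = names(gsize),
                               n_days = length(days)),
                 subject_means = data.frame(
                   subject = wide$subject, group = wide$group,
                   score = rowMeans(wide[day_cols])),
                 test = test),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the n x D repeated-measures matrix.
gg_epsilon <- function(m, groups) {
  D <- ncol(m)
  groups <- as.factor(groups)
  pooled <- matrix(0, D, D)
  dfsum <- 0
  for (g in levels(groups)) {
    mg <- m[groups == g, , drop = FALSE]
    if (nrow(mg) < 2L) next
    pooled <- pooled + stats::cov(mg) * (nrow(mg) - 1L)
    dfsum <- dfsum + nrow(mg) - 1L
  }
  S <- pooled / dfsum
  # orthonormal contrasts over the D occasions
  C <- t(stats::contr.helmert(D)) / sqrt(colSums(stats::contr.helmert(D)^2))
  SS <- C %*% S %*% t(C)
  min(sum(diag(SS))^2 / ((D - 1) * sum(SS^2)), 1)
}

#' Interpretation band for partial eta squared
#'
#' Below 0.06 small, 0.06 to below 0.14 moderate, 0.14 and above large.
#'
#' @param eta_sq partial eta squared in \[0, 1\].
#' @return character band.
#' @export
eta_sq_band <- function(eta_sq) {
  if (any(eta_sq < 0 | eta_sq > 1, na.rm = TRUE)) {
    stop("partial eta squared must lie in [0, 1]")
  }
  vapply(eta_sq, function(e) {
    if (is.na(e)) NA_character_
    else if (e < 0.06) "small"
    else if (e < 0.14) "moderate"
    else "large"
  }, character(1L))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA: %s (%d groups x %d days)\n",
              x$test, length(x$design$n_per_group), x$design$n_days))
  print(x$effects[c("effect", "df", "df_error", "F", "p", "p_gg",
                    "partial_eta_sq", "eta_band")], row.names = FALSE)
  if (!is.na(x$epsilon_gg)) {
    cat(sprintf("Greenhouse-Geisser epsilon = %.3f (applied to within effects)\n",
                x$epsilon_gg))
  }
  invisible(x)
}

#' Scheffe post hoc contrasts between groups
#'
#' All pairwise group contrasts tested against the Scheffe criterion: the
#' contrast F statistic divided by (g - 1) is referred to the
#' F(g - 1, df_error) distribution, which controls the family-wise error
#' over every possible contrast. Cohen's d uses the pooled SD of the two
#' groups; |d| bands: below 0.2 trivial, to below 0.5 small, to below 0.8
#' moderate, 0.8 and above large.
#'
#' @param x an [rm_anova()] fit (contrasts on per-subject means across
#'   days) or a numeric vector of subject-level values.
#' @param groups group labels, required when `x` is a numeric vector.
#' @return data.frame of contrasts: `group_a`, `group_b`, `mean_diff`,
#'   `cohens_d`, `d_band`, `F_contrast`, `p_scheffe`.
#' @export
scheffe_posthoc <- function(x, groups = NULL) {
  if (inherits(x, "rm_anova")) {
    values <- x$subject_means$score
    groups <- x$subject_means$group
  } else {
    values <- as.numeric(x)
    if (is.null(groups)) stop("supply group labels")
  }
  groups <- as.factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop("Scheffe contrasts need >= 2 groups")
  ns <- tapply(values, groups, length)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  df_err <- sum(ns) - g
  mse <- sum((ns - 1L) * vars) / df_err

  combs <- utils::combn(levels(groups), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    diff <- means[[a]] - means[[b]]
    pooled_sd <- sqrt(((ns[[a]] - 1L) * vars[[a]] + (ns[[b]] - 1L) * vars[[b]]) /
                        (ns[[a]] + ns[[b]] - 2L))
    d <- if (pooled_sd > 0) diff / pooled_sd else 0
    f_con <- diff^2 / (mse * (1 / ns[[a]] + 1 / ns[[b]]))
    p <- stats::pf(f_con / (g - 1L), g - 1L, df_err, lower.tail = FALSE)
    data.frame(group_a = a, group_b = b, mean_diff = diff,
               cohens_d = d, d_band = cohens_d_band(d),
               F_contrast = f_con, p_scheffe = p)
  }))
  rownames(out) <- NULL
  out
}

#' Interpretation band for Cohen's d
#'
#' @param d Cohen's d (sign ignored).
#' @return character: `"trivial"`, `"small"`, `"moderate"` or `"large"`.
#' @export
cohens_d_band <- function(d) {
  vapply(abs(d), function(a) {
    if (a < 0.2) "trivial"
    else if (a < 0.5) "small"
    else if (a < 0.8) "moderate"
    else "large"
  }, character(1L))
}

#' First-to-last-day change scores compared across groups
#'
#' Computes each subject's improvement from the first to the last day
#' (day-1 mean minus last-day mean, sign-flipped for tests where higher
#' scores are better so that positive change always means improvement) and
#' compares the group means with a one-way ANOVA plus Scheffe contrasts.
#'
#' @param ds a [trial_data()] dataset.
#' @param test test label.
#' @return a `change_scores` object: per-subject changes, per-group
#'   summary, one-way ANOVA F/p/partial eta squared (NA with a single
#'   group) and Scheffe contrasts.
#' @export
change_scores <- function(ds, test) {
  stopifnot(inherits(ds, "trial_data"))
  dm <- day_means(ds, test)
  days <- sort(unique(dm$day))
  if (length(days) < 2L) stop("change scores need >= 2 days")
  first <- dm[dm$day == days[1L], ]
  last <- dm[dm$day == days[length(days)], ]
  subjects <- intersect(first$subject, last$subject)
  hib <- attr(ds, "higher_is_better")[[test]]
  sgn <- if (isTRUE(hib)) -1 else 1
  chg <- data.frame(
    subject = subjects,
    group = first$group[match(subjects, first$subject)],
    change = sgn * (first$score[match(subjects, first$subject)] -
                      last$score[match(subjects, last$subject)]))

  by_group <- do.call(rbind, lapply(split(chg, chg$group), function(d) {
    data.frame(group = d$group[1L], n = nrow(d), mean_change = mean(d$change),
               sd_change = stats::sd(d$change))
  }))
  rownames(by_group) <- NULL

  anova_row <- NULL; contrasts <- NULL
  if (length(unique(chg$group)) >= 2L) {
    fit <- stats::aov(change ~ group, data = chg)
    tab <- summary(fit)[[1L]]
    anova_row <- data.frame(F = tab[1L, "F value"], df = tab[1L, "Df"],
                            df_error = tab[2L, "Df"], p = tab[1L, "Pr(>F)"],
                            partial_eta_sq = tab[1L, "Sum Sq"] /
                              sum(tab[, "Sum Sq"]))
    contrasts <- scheffe_posthoc(chg$change, chg$group)
  }
  structure(list(test = test, changes = chg, by_group = by_group,
                 anova = anova_row, contrasts = contrasts,
                 first_day = days[1L], last_day = days[length(days)]),
            class = "change_scores")
}

#' @export
print.change_scores <- function(x, ...) {
  cat(sprintf("First-to-last-day change (%s, day %d -> %d; positive = improvement):\n",
              x$test, x$first_day, x$last_day))
  print(x$by_group, row.names = FALSE)
  if (!is.null(x$anova)) {
    cat(sprintf("One-way ANOVA across groups: F(%d, %d) = %.3f, p = %.4g\n",
                x$anova$df, x$anova$df_error, x$anova$F, x$anova$p))
  } else {
    cat("Single group: descriptive change only.\n")
  }
  invisible(x)
}
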