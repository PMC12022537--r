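# Shared fixture builders: everything generated in code, no stored data.

# minimal complete design: n subjects, one group, one test, D days x 2 trials
toy_trials <- function(n = 4L, days = 3L, test = "stroop", group = "g1",
                       seed = 1L, base = 20, subject_sd = 3, noise_sd = 1) {
  set.seed(seed)
  b <- rnorm(n, 0, subject_sd)
  grid <- expand.grid(subject = sprintf("s%02d", seq_len(n)),
                      day = seq_len(days), trial = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- group
  grid$test <- test
  grid$score <- base + b[match(grid$subject, sprintf("s%02d", seq_len(n)))] +
    rnorm(nrow(grid), 0, noise_sd)
  trial_data(grid)
}

# a paired_comparison straight from two vectors
pair_of <- function(x, y, label = "toy 1", kind = "intraday") {
  paired_comparison(x, y, label = label, kind = kind, test = "toy")
}

# one-group, one-test, zero-learning simulation config (null model)
null_config <- function(n = 65L, subject_sd = 3, error_sd = 1.5,
                        base = 20, n_days = 5L) {
  sim_config(data.frame(label = "all", n = as.integer(n)),
             list(test_spec("t1", "s", FALSE, baseline = c(all = base),
                            subject_sd = subject_sd, amp_interday = 0,
                            amp_intraday = 0, decay = 0,
                            error_sd = error_sd)),
             n_days = n_days, n_trials_per_day = 2L)
}

# brute-force two-way (subjects x occasions) sums of squares, written as
# explicit elementwise loops so it shares no code with ms_decomposition()
brute_force_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_total <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_total <- ss_total + (m[i, j] - grand)^2
  }
  list(ss_rows = ss_rows, ss_cols = ss_cols,
       ss_error = ss_total - ss_rows - ss_cols, ss_total = ss_total,
       msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1)))
}

# brute-force mixed-design (group between, day within) cell-mean SS
brute_force_mixed_ss <- function(scores, group, subject, day) {
  grand <- mean(scores)
  gl <- unique(group); dl <- sort(unique(day)); sl <- unique(subject)
  D <- length(dl)
  g_of <- function(s) group[match(s, subject)]
  mean_g <- sapply(gl, function(g) mean(scores[group == g]))
  mean_d <- sapply(dl, function(d) mean(scores[day == d]))
  mean_s <- sapply(sl, function(s) mean(scores[subject == s]))
  n_g <- sapply(gl, function(g) length(unique(subject[group == g])))

  ss_group <- sum(n_g * D * (mean_g - grand)^2)
  ss_subj <- 0
  for (i in seq_along(sl)) {
    ss_subj <- ss_subj + D * (mean_s[i] - mean_g[match(g_of(sl[i]), gl)])^2
  }
  ss_day <- sum(length(sl) * (mean_d - grand)^2)
  ss_gd <- 0
  for (gi in seq_along(gl)) for (di in seq_along(dl)) {
    cell <- mean(scores[group == gl[gi] & day == dl[di]])
    ss_gd <- ss_gd + n_g[gi] *
      (cell - mean_g[gi] - mean_d[di] + grand)^2
  }
  ss_total <- sum((scores - grand)^2)
  lapply(list(ss_group = ss_group, ss_subj = ss_subj, ss_day = ss_day,
              ss_gd = ss_gd,
              ss_err = ss_total - ss_group - ss_subj - ss_day - ss_gd),
         unname)
}

# learning_curve object built by hand, for exercising the decision rule
# on crafted p-value / MAPE series
curve_from_series <- function(p_adjusted, mape,
                              bias = rep(1, length(p_adjusted))) {
  k <- length(p_adjusted)
  cmp <- data.frame(label = paste0("toy ", 1:k, "_", 2:(k + 1)),
                    day_from = 1:k, day_to = 2:(k + 1), n = 65L,
                    bias = bias, p_raw = p_adjusted,
                    p_adjusted = p_adjusted, mape = mape,
                    mdc = rep(1, k))
  structure(list(test = "toy", group = "overall",
                 days = data.frame(day = 1:(k + 1), mean = 0, sd = 1,
                                   sem_of_mean = 0.1, n = 65L),
                 comparisons = cmp, multiplicity = "none"),
            class = "learning_curve")
}
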