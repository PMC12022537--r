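test_that("the generator is deterministic given a seed and restores RNG state", {
  cfg <- cohort_preset()
  set.seed(321)
  before <- .Random.seed
  d1 <- simulate_cohort(cfg, seed = 7)
  expect_identical(.Random.seed, before)   # caller's stream untouched
  d2 <- simulate_cohort(cfg, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(d1$score, d3$score))
})

test_that("preset matches the intended study design", {
  cfg <- cohort_preset()
  expect_equal(cfg$groups$n, c(22L, 20L, 23L))
  expect_equal(cfg$n_days, 5L)
  expect_equal(cfg$n_trials_per_day, 2L)
  expect_length(cfg$tests, 5L)
  ruler <- cfg$tests[[which(vapply(cfg$tests, `[[`, "", "name") ==
                              "ruler_drop")]]
  expect_equal(ruler$censor_value, 51)

  ds <- simulate_cohort(cfg, seed = 1)
  expect_equal(length(unique(ds$subject)), 65L)
  expect_equal(sort(unique(ds$group)),
               sort(c("children", "young_adults", "older_adults")))
  dg <- design_of(ds)
  expect_true(all(dg$n_days == 5L) && all(dg$n_trials_per_day == 2L))
})

test_that("no-learning configuration produces flat means and near-zero bias", {
  ds <- simulate_cohort(null_config(n = 300L), seed = 11)
  pairs <- make_pairs(ds, "t1", "interday")
  biases <- vapply(pairs[1:4], function(p) paired_bias_test(p)$bias,
                   numeric(1))
  # true bias is 0; sampling SE of a day-mean difference at n=300 is ~0.09
  expect_true(all(abs(biases) < 0.3))
})

test_that("variance components set the intraday ICC", {
  ds <- simulate_cohort(null_config(n = 500L, subject_sd = 3, error_sd = 1),
                        seed = 19)
  p <- make_pairs(ds, "t1", "intraday")[[1L]]
  est <- icc_agreement(ms_decomposition(p))$estimate
  expect_lt(abs(est - 0.9), 0.03)   # sigma_s^2 / (sigma_s^2 + sigma_e^2)
})

test_that("censoring respects the recorded-value convention", {
  g <- data.frame(label = "all", n = 400L)
  ts <- test_spec("ruler", "cm", FALSE, baseline = c(all = 45),
                  subject_sd = 5, amp_interday = 0, amp_intraday = 0,
                  decay = 0, error_sd = 5,
                  floor = 1, ceiling = 50, censor_value = 51)
  ds <- simulate_cohort(sim_config(g, list(ts), n_days = 2L), seed = 23)
  expect_true(all(ds$score <= 51))
  # values strictly between the ceiling and the censor value cannot occur
  expect_false(any(ds$score > 50 & ds$score < 51))
  expect_gt(sum(ds$score == 51), 0)   # censoring actually engaged
  expect_true(all(ds$score >= 1))
})

test_that("learning direction follows the scoring direction", {
  cfg <- cohort_preset()
  ds <- simulate_cohort(cfg, seed = 3)
  # time-scored: early sessions slower (higher); hits: early sessions lower
  dm_t <- day_means(ds, "trail_making")
  dm_h <- day_means(ds, "choice_reaction")
  expect_gt(mean(dm_t$score[dm_t$day == 1]), mean(dm_t$score[dm_t$day == 5]))
  expect_lt(mean(dm_h$score[dm_h$day == 1]), mean(dm_h$score[dm_h$day == 5]))
  # trial 1 is worse than trial 2 on day 1 (intraday learning)
  d1 <- ds[ds$test == "trail_making" & ds$day == 1L, ]
  expect_gt(mean(d1$score[d1$trial == 1L]), mean(d1$score[d1$trial == 2L]))
})

test_that("analytic truth records the implied ICC and bias decay", {
  g <- data.frame(label = "all", n = 10L)
  ts <- test_spec("t1", "s", FALSE, baseline = c(all = 20), subject_sd = 2,
                  amp_interday = 6, amp_intraday = 2, decay = 0.5,
                  error_sd = 2)
  tr <- sim_truth(sim_config(g, list(ts)))$t1
  expect_equal(tr$icc_day, rep(0.5, 5))   # equal variances
  lam <- 0.5
  expect_equal(tr$groups$all$bias,
               7 * (exp(-lam * (0:3)) - exp(-lam * (1:4))),
               tolerance = 1e-12)

  # decay 0 implies no day-to-day change
  ts0 <- test_spec("t1", "s", FALSE, baseline = c(all = 20), subject_sd = 2,
                   amp_interday = 6, amp_intraday = 2, decay = 0,
                   error_sd = 2)
  tr0 <- sim_truth(sim_config(g, list(ts0)))$t1
  expect_equal(tr0$groups$all$bias, rep(0, 4))

  # pipeline estimates converge to the recorded truth at large n
  gg <- data.frame(label = "all", n = 2000L)
  cfg <- sim_config(gg, list(ts))
  ds <- simulate_cohort(cfg, seed = 29)
  pairs <- make_pairs(ds, "t1", "interday")
  est <- vapply(pairs[1:4], function(p) paired_bias_test(p)$bias, numeric(1))
  truth <- sim_truth(cfg)$t1$groups$all$bias
  expect_true(all(abs(est - truth) < 4 * 2 / sqrt(2000) + 0.05))
})

test_that("shrinking error narrows the limits of agreement across days", {
  g <- data.frame(label = "all", n = 800L)
  ts <- test_spec("t1", "s", FALSE, baseline = c(all = 30), subject_sd = 5,
                  amp_interday = 0, amp_intraday = 0, decay = 0,
                  error_sd = c(3, 2.5, 2, 1.5, 1))
  ds <- simulate_cohort(sim_config(g, list(ts)), seed = 37)
  widths <- vapply(make_pairs(ds, "t1", "intraday"), function(p) {
    ba <- bland_altman(p)
    ba$loa_high - ba$loa_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("simulation configs round-trip through YAML and JSON", {
  cfg <- cohort_preset()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_sim_config(cfg, path)
    back <- read_sim_config(path)
    expect_equal(back$groups$n, cfg$groups$n)
    expect_equal(back$n_days, cfg$n_days)
    expect_equal(length(back$tests), length(cfg$tests))
    expect_equal(back$tests[[1L]]$baseline, cfg$tests[[1L]]$baseline)
    expect_equal(back$tests[[1L]]$censor_value, cfg$tests[[1L]]$censor_value)
    # identical data from the restored config
    expect_identical(as.data.frame(simulate_cohort(back, seed = 5)),
                     as.data.frame(simulate_cohort(cfg, seed = 5)))
  }
})

test_that("invalid configurations are rejected", {
  g <- data.frame(label = "all", n = 5L)
  expect_error(test_spec("t", "s", FALSE, baseline = c(all = 1),
                         subject_sd = 0, amp_interday = 0, amp_intraday = 0,
                         decay = 0, error_sd = 1))
  expect_error(test_spec("t", "s", FALSE, baseline = c(all = 1),
                         subject_sd = 1, amp_interday = 0, amp_intraday = 0,
                         decay = 0, error_sd = 1, ceiling = 50,
                         censor_value = 49), ">= ceiling")
  ts <- test_spec("t", "s", FALSE, baseline = c(other = 1), subject_sd = 1,
                  amp_interday = 0, amp_intraday = 0, decay = 0, error_sd = 1)
  expect_error(sim_config(g, list(ts)), "lacks baselines")
})
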