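test_that("mean-square decomposition matches hand values on toy columns", {
  # identical columns: no occasion or residual variance
  d0 <- ms_decomposition(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d0$msc, 0)
  expect_equal(d0$mse, 0)
  expect_equal(d0$msr, 2 * var(c(1, 2, 3)))

  # constant shift: all non-row variance is in the occasion term
  d1 <- ms_decomposition(c(1, 2, 3), c(2, 3, 4))
  expect_equal(d1$msc, 1.5)   # n * (shift/2)^2 * 2 = 3 * 0.5 ... = 1.5
  expect_equal(d1$mse, 0)
  expect_equal(d1$msr, 4 / 2)

  bf <- brute_force_ss(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(d1$msr, bf$msr)
  expect_equal(d1$msc, bf$msc)
  expect_equal(d1$mse, bf$mse)
})

test_that("sum-of-squares identity holds on random matrices", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(3:10, 1L)
    m <- matrix(rnorm(n * 2, 20, 5), ncol = 2)
    d <- ms_decomposition(m[, 1L], m[, 2L])
    bf <- brute_force_ss(m)
    expect_equal(d$ss_rows + d$ss_cols + d$ss_error, d$ss_total,
                 tolerance = 1e-10)
    expect_equal(d$msr, bf$msr, tolerance = 1e-10)
    expect_equal(d$msc, bf$msc, tolerance = 1e-10)
    expect_equal(d$mse, bf$mse, tolerance = 1e-10)
    expect_equal(d$df_rows, n - 1L)
    expect_equal(d$df_error, n - 1L)
  }
})

test_that("ICC(A,1) matches frozen reference values with F-based CI", {
  # expected values computed independently (variance-component reference
  # implementation, cross-checked against pingouin's ICC(A,1) row)
  p1 <- pair_of(c(10, 12, 14, 16), c(11, 12, 15, 15))
  r1 <- icc_agreement(ms_decomposition(p1))
  expect_equal(r1$estimate, 0.9302325581395348, tolerance = 1e-12)
  expect_equal(r1$ci_low, 0.3477242649351201, tolerance = 1e-9)
  expect_equal(r1$ci_high, 0.9953095296138788, tolerance = 1e-9)
  expect_equal(r1$band, "excellent")

  x2 <- c(21.52, 14.8, 23.75, 24.7, 10.24, 13.49, 20.64, 18.42)
  y2 <- c(22.49, 14.52, 26.07, 26.87, 11.34, 16.18, 22.34, 18.13)
  r2 <- icc_agreement(ms_decomposition(pair_of(x2, y2)))
  expect_equal(r2$estimate, 0.9525703258063238, tolerance = 1e-12)
  expect_equal(r2$ci_low, 0.4655506086310848, tolerance = 1e-9)
  expect_equal(r2$ci_high, 0.9919200636451229, tolerance = 1e-9)

  # x == y with subject variance: both variants give exactly 1
  pid <- pair_of(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_agreement(pid, variant = "standard")$estimate, 1)
  expect_equal(icc_agreement(pid, variant = "paper")$estimate, 1)
})

test_that("standard ICC matches a brute-force variance-component oracle", {
  # one-way decomposition by explicit variance components on the same
  # matrix: sigma2_r = (MSR - MSE)/k, sigma2_c = (MSC - MSE)/n,
  # ICC(A,1) = sigma2_r / (sigma2_r + sigma2_c + MSE)
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:12, 1L)
    x <- rnorm(n, 30, 6); y <- x + rnorm(n, 1, 2)
    bf <- brute_force_ss(cbind(x, y))
    s2r <- (bf$msr - bf$mse) / 2
    s2c <- (bf$msc - bf$mse) / n
    oracle <- unname(s2r / (s2r + s2c + bf$mse))
    est <- icc_agreement(ms_decomposition(pair_of(x, y)))$estimate
    expect_equal(est, oracle, tolerance = 1e-10)
  }
})

test_that("simulated variance components are recovered by the ICC", {
  set.seed(31)
  n <- 500
  subj <- rnorm(n, 0, 3)
  x <- 20 + subj + rnorm(n, 0, 1)
  y <- 20 + subj + rnorm(n, 0, 1)
  est <- icc_agreement(ms_decomposition(pair_of(x, y)))$estimate
  expect_lt(abs(est - 0.9), 0.03)   # true ICC = 9 / (9 + 1)
})

test_that("agreement ICC penalizes a systematic shift; ranking is unchanged", {
  set.seed(5)
  x <- rnorm(12, 50, 8)
  y0 <- x + rnorm(12, 0, 1)
  prev <- icc_agreement(ms_decomposition(pair_of(x, y0)))$estimate
  for (c_shift in c(2, 5, 10)) {
    est <- icc_agreement(ms_decomposition(pair_of(x, y0 + c_shift)))$estimate
    expect_lt(est, prev)
    prev <- est
    expect_equal(order(y0 + c_shift), order(y0))
  }
})

test_that("ICC is scale invariant while SEM and MDC are equivariant", {
  set.seed(8)
  x <- rnorm(10, 30, 5); y <- x + rnorm(10, 1, 2)
  a <- 3.7
  for (variant in c("standard", "paper")) {
    e1 <- icc_agreement(ms_decomposition(pair_of(x, y)), variant)$estimate
    e2 <- icc_agreement(ms_decomposition(pair_of(a * x, a * y)), variant)$estimate
    expect_equal(e1, e2, tolerance = 1e-10)
  }
  icc <- icc_agreement(ms_decomposition(pair_of(x, y)))$estimate
  expect_equal(sem_from(a * sd(x - y), icc), a * sem_from(sd(x - y), icc),
               tolerance = 1e-12)
})

test_that("SEM and MDC formulas are exact", {
  expect_equal(sem_from(5, 1), 0)
  expect_equal(sem_from(1, 0), 1)
  expect_equal(sem_from(2.83, 0.97), 2.83 * sqrt(0.03))
  expect_equal(round(sem_from(2.83, 0.97), 3), 0.49)
  expect_error(sem_from(1, -0.1), "\\[0, 1\\]")
  expect_error(sem_from(-1, 0.5), ">= 0")

  expect_equal(mdc_from(0), 0)
  expect_equal(round(mdc_from(0.91), 2), 2.52)
  expect_equal(round(mdc_from(0.40), 2), 1.11)
  expect_error(mdc_from(-0.1), ">= 0")

  # MDC/SD closed form: 2.7719 * sqrt(1 - ICC)
  set.seed(17)
  for (rep in 1:10) {
    sd_b <- runif(1, 0.5, 10); icc <- runif(1)
    expect_equal(mdc_from(sem_from(sd_b, icc)) / sd_b,
                 1.96 * sqrt(2) * sqrt(1 - icc), tolerance = 1e-12)
  }
})

test_that("ICC bands follow the interpretation thresholds", {
  expect_equal(icc_band(0.39), "poor")
  expect_equal(icc_band(0.49999), "poor")
  expect_equal(icc_band(0.50), "moderate")
  expect_equal(icc_band(0.75), "good")
  expect_equal(icc_band(0.90), "excellent")
  expect_equal(icc_band(c(0.2, 0.6, 0.8, 0.95)),
               c("poor", "moderate", "good", "excellent"))
  expect_error(icc_band(1.2), "\\[-1, 1\\]")
})

test_that("degenerate decompositions are rejected, not silently NaN", {
  # all scores identical: msr = mse = msc = 0, denominator 0
  d <- ms_decomposition(c(2, 2, 2), c(2, 2, 2))
  expect_error(icc_agreement(d), "zero denominator")
  expect_error(ms_decomposition(c(1), c(2)), "n >= 2")
})
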