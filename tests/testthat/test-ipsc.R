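make_measurement <- function(time, trace) {
  structure(list(time = time, trace = trace), class = "ipsc_measurement")
}

test_that("trial averaging subtracts baseline and preserves identical trials", {
  time <- seq(-0.1, 0.6, by = 1e-4)
  tmpl <- 5 + 20 * exp(-pmax(time, 0) / 0.05) * (time >= 0)
  trials <- matrix(tmpl, length(time), 5)
  m <- average_trials(trials, time)
  expect_equal(m$baseline, 5, tolerance = 1e-12)
  expect_equal(m$trace, tmpl - 5, tolerance = 1e-12)
  # single trial returns itself, baseline-subtracted
  m1 <- average_trials(matrix(tmpl, ncol = 1), time)
  expect_equal(m1$trace, tmpl - 5)
  expect_error(average_trials(list(tmpl, tmpl[-1]), time), "mismatched")
})

test_that("trial-average error shrinks like 1/sqrt(n)", {
  set.seed(13)
  time <- seq(-0.1, 0.4, by = 1e-3)
  tmpl <- 30 * exp(-pmax(time, 0) / 0.05) * (time >= 0)
  rms <- vapply(c(4, 64), function(n) {
    trials <- matrix(tmpl, length(time), n) +
      matrix(rnorm(length(time) * n, 0, 5), length(time), n)
    sqrt(mean((average_trials(trials, time)$trace - tmpl)^2))
  }, numeric(1))
  expect_lt(rms[2], rms[1] / 2)
})

test_that("charge integrates the outward current", {
  # 10 pA rectangular pulse lasting 1 s -> 10 pA*s
  time <- seq(-0.1, 1.2, by = 1e-4)
  rect <- ifelse(time >= 0 & time <= 1, 10, 0)
  m <- make_measurement(time, rect)
  expect_equal(charge(m, window = c(0, 1.2)), 10, tolerance = 1e-3)
  # single-exponential event: integral = A * tau
  expdec <- ifelse(time >= 0, 25 * exp(-time / 0.04), 0)
  expect_equal(charge(make_measurement(time, expdec), c(0, 1.2)),
               25 * 0.04, tolerance = 1e-3)
  expect_error(charge(m, window = c(0, 5)), "outside")
})

test_that("charge is linear and additive over non-overlapping windows", {
  set.seed(14)
  time <- seq(-0.05, 0.5, by = 1e-4)
  tr <- pmax(rnorm(length(time), 2, 3), 0)
  m <- make_measurement(time, tr)
  expect_equal(charge(make_measurement(time, 3 * tr), c(0, 0.5)),
               3 * charge(m, c(0, 0.5)), tolerance = 1e-10)
  expect_equal(charge(m, c(0, 0.2)) + charge(m, c(0.2, 0.5)),
               charge(m, c(0, 0.5)), tolerance = 1e-10)
})

test_that("the 10 pA inclusion filter keeps boundary IPSCs and never adds", {
  mk <- function(pk) structure(list(peak = pk), class = "ipsc_measurement")
  ms <- list(mk(9.9), mk(10.0), mk(25), mk(3))
  kept <- include_filter(ms)
  expect_equal(vapply(kept, `[[`, numeric(1), "peak"), c(10, 25))
  # surviving count equals a direct count; order-independent
  expect_length(include_filter(rev(ms)), 2)
  expect_lte(length(include_filter(ms)), length(ms))
})

test_that("decomposition reproduces hand-computed percentages and sums to 100", {
  d <- decompose(40.6, 18.4, 4.07)
  expect_equal(d$somatic_percent, 100 * (40.6 - 18.4) / 40.6,
               tolerance = 1e-12)
  expect_equal(d$distal_percent, 100 * (18.4 - 4.07) / 40.6,
               tolerance = 1e-12)
  expect_equal(d$other_percent, 100 * 4.07 / 40.6, tolerance = 1e-12)
  expect_equal(d$somatic_percent + d$distal_percent + d$other_percent, 100)
  # pure somatic inhibition
  d2 <- decompose(10, 0, 0)
  expect_equal(d2$somatic_percent, 100)
  expect_equal(d2$distal_percent, 0)
  # sums to 100 for arbitrary (even non-physical) charges
  set.seed(15)
  for (i in 1:20) {
    q <- runif(3, 0, 50)
    d3 <- suppressWarnings(decompose(q[1], q[2], q[3]))
    expect_equal(d3$somatic_percent + d3$distal_percent + d3$other_percent,
                 100, tolerance = 1e-9)
  }
  expect_warning(decompose(10, 12, 1), "ordering")
  expect_error(decompose(0, 0, 0), "positive")
})

test_that("noiseless scenarios are decomposed exactly to the generator fractions", {
  sc <- default_pc_scenario(trial_noise_sd = 0, n_trials = 1)
  exp_ <- simulate_ipsc_experiment(sc, seed = 1)
  res <- measure_ipsc_experiment(exp_)
  r <- sc$residual_fraction
  fd <- component_charge(sc$dendritic) /
    (component_charge(sc$somatic) + component_charge(sc$dendritic))
  expect_equal(res$decomposition$distal_percent, 100 * fd * (1 - r),
               tolerance = 1e-3)
  expect_equal(res$decomposition$somatic_percent, 100 * (1 - fd) * (1 - r),
               tolerance = 1e-3)
  expect_equal(res$decomposition$other_percent, 100 * r, tolerance = 1e-3)
})

test_that("a paired within-slice comparison recovers a constructed offset", {
  set.seed(16)
  other <- rgamma(8, shape = 4, scale = 2.5)
  pairs <- cbind(ppv = other + 12, other = other)
  out <- compare_within_slice(pairs)
  expect_equal(out$mean_difference, 12, tolerance = 1e-9)
  expect_lt(out$test$p_value, 0.05)
  # identical pairs: difference 0, non-significant by construction
  same <- cbind(other, other)
  out2 <- compare_within_slice(same)
  expect_equal(out2$mean_difference, 0)
  expect_equal(out2$test$p_value, 1)
  expect_error(compare_within_slice(pairs[0, , drop = FALSE]), "pair")
})

test_that("pPV-targeting boost is detected by a one-sided signed-rank test at n = 8", {
  # effect size from the published group means (23.3 vs 9.69 pA*s)
  set.seed(17)
  other <- rgamma(8, shape = 5, scale = 9.69 / 5)
  ppv <- other * 23.3 / 9.69 + rnorm(8, 0, 2)
  res <- run_test("WSR", list(x = ppv, y = other), alternative = "greater")
  expect_lt(res$p_value, 0.05)
})
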