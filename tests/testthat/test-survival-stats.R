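test_that("Cox wrapper recovers a known rate ratio and flags degenerate designs", {
  set.seed(7)
  x <- rep(c(0, 1), each = 500)
  t <- rexp(1000, rate = ifelse(x == 1, 2, 1))
  f <- fit_cox(x, t, rep(1, 1000))
  expect_gt(exp(f$beta), 1.8)
  expect_lt(exp(f$beta), 2.2)
  expect_false(f$degenerate)

  # null covariate: |beta| < 2 SE in at least 90% of replicates
  set.seed(8)
  ok <- replicate(50, {
    d <- exp_surv_cohort(200, beta = 0)
    f <- fit_cox(d$x, d$time, d$event)
    abs(f$beta) < 2 * f$se
  })
  expect_gte(mean(ok), 0.9)

  fc <- fit_cox(rep(1, 50), rexp(50) + 0.1, rep(1, 50))
  expect_true(fc$degenerate)
  expect_equal(fc$beta, 0)
  expect_equal(fc$se, Inf)
  expect_error(fit_cox(rnorm(20), rexp(20) + 0.1, rep(0, 20)), "no events")
})

test_that("signed concordance probability matches the pairwise oracle", {
  # three patients with linear predictors 0, 1, 2, lower covariate better
  x <- c(0, 1, 2)
  cp <- concordance_probability(1, x, "lower")
  expect_equal(cp, (1 / (1 + exp(-1)) + 1 / (1 + exp(-2)) + 1 / (1 + exp(-1))) / 3)
  expect_equal(cp, 0.780971, tolerance = 1e-5)

  # zero coefficient gives 0.5 exactly, as do all-tied covariates
  expect_identical(concordance_probability(0, rnorm(50), "higher"), 0.5)
  expect_identical(concordance_probability(1.3, rep(2.5, 30), "lower"), 0.5)

  set.seed(9)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    x <- round(rnorm(n), 2) # rounding creates occasional ties
    beta <- rnorm(1)
    dir <- sample(c("higher", "lower"), 1)
    expect_equal(concordance_probability(beta, x, dir),
                 cp_oracle(beta, x, dir), tolerance = 1e-12)
    # flipping the direction reflects the estimate about 0.5
    expect_equal(concordance_probability(beta, x, "higher"),
                 1 - concordance_probability(beta, x, "lower"),
                 tolerance = 1e-12)
  }
})

test_that("patient bootstrap is reproducible and degenerates correctly", {
  d <- exp_surv_cohort(80, beta = 0.5)
  const <- function(df) 0.7
  r <- bootstrap_ci(const, d, n_boot = 50, seed = 1)
  expect_equal(r$ci_low, 0.7)
  expect_equal(r$ci_high, 0.7)
  expect_true(r$significant)

  stat <- function(df) {
    f <- fit_cox(df$x, df$time, df$event)
    concordance_probability(f$beta, df$x, "lower")
  }
  r1 <- bootstrap_ci(stat, d, n_boot = 200, seed = 42)
  r2 <- bootstrap_ci(stat, d, n_boot = 200, seed = 42)
  expect_identical(r1$boot_values, r2$boot_values)
  expect_identical(r1$cp, r2$cp)
  expect_true(r1$ci_low <= r1$cp + 0.02 && r1$cp - 0.02 <= r1$ci_high)

  fails <- function(df) stop("boom")
  expect_error(bootstrap_ci(fails, d, n_boot = 20, seed = 1), "failed")
})

test_that("Kaplan-Meier median matches closed forms and handles non-reachable curves", {
  set.seed(10)
  t <- rexp(2000, rate = log(2) / 10)
  km <- km_median(t, rep(1, 2000))
  expect_gt(km$median, 9.5)
  expect_lt(km$median, 10.5)
  expect_true(km$ci_low < km$median && km$median < km$ci_high)

  # uncensored odd-n sample: first sorted time with survival <= 0.5
  tt <- c(3, 1, 9, 7, 5)
  expect_equal(km_median(tt, rep(1, 5))$median, 5)

  # heavy censoring: curve never reaches 0.5, median missing
  km2 <- km_median(c(1, 100, 100, 100, 100), c(1, 0, 0, 0, 0))
  expect_true(is.na(km2$median))
  expect_error(km_median(c(1, 2, 3), c(0, 0, 0)), "no events")
})

test_that("hazard ratio is symmetric under relabelling and recovers a known ratio", {
  set.seed(12)
  tA <- rexp(300, 1); tB <- rexp(300, 1.5)
  eA <- rep(1, 300); eB <- rep(1, 300)
  hab <- hazard_ratio(tA, eA, tB, eB)
  hba <- hazard_ratio(tB, eB, tA, eA)
  expect_equal(hab$hr, 1 / hba$hr, tolerance = 1e-8)

  # identical arms give HR 1 up to optimiser tolerance
  hid <- hazard_ratio(tA, eA, tA, eA)
  expect_equal(hid$hr, 1, tolerance = 1e-6)

  # simulated rate ratio 0.71 (test-trial PFS HR regime)
  set.seed(13)
  t1 <- rexp(400, 0.71); t2 <- rexp(400, 1)
  h <- hazard_ratio(t1, rep(1, 400), t2, rep(1, 400))
  expect_gt(h$hr, 0.6); expect_lt(h$hr, 0.85)
  expect_true(h$ci_low < h$hr && h$hr < h$ci_high)
})

test_that("cp_analysis combines the Cox fit, signed CP and bootstrap", {
  set.seed(14)
  d <- exp_surv_cohort(150, beta = 0.8)
  r <- cp_analysis(d$x, d$time, d$event, direction = "lower",
                   n_boot = 200, seed = 3)
  expect_gt(r$cp, 0.5)
  expect_true(r$significant)
  expect_equal(r$direction, "lower")
  # direction contradicting the true effect lands below 0.5
  r2 <- cp_analysis(d$x, d$time, d$event, direction = "higher",
                    n_boot = 200, seed = 3)
  expect_lt(r2$cp, 0.5)
})
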