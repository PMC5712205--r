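test_that("progression rule fires at the first qualifying scan", {
  expect_equal(apply_progression(c(5.0, 4.0, 4.9), 0.2), 3L)
  # nadir 4.0, next scan 4.9: 4.9 >= 1.2 * 4.0 triggers PD
  expect_equal(apply_progression(c(6, 4.0, 4.9), 0.2), 3L)
  expect_true(is.na(apply_progression(c(9, 8, 7, 6.5), 0.2)))
  # zero threshold degenerates to the first uptick from the nadir
  expect_equal(apply_progression(c(5, 4, 4.01), 0), 3L)
  # baseline scan can never trigger progression
  expect_equal(apply_progression(c(2, 2.5), 0.2), 2L)
  expect_true(is.na(apply_progression(7.5)))
  expect_error(apply_progression(numeric(0)), "empty")
})

test_that("noise-free, zero-variability cohorts lie exactly on the model curve", {
  spec <- nsclc_arm_spec("docetaxel", n_patients = 15, seed = 1,
                         omega2 = c(0, 0, 0), sigma = 0,
                         death_during_imaging_prob = 0)
  coh <- generate_cohort(spec)
  p <- kinetic_params(exp(spec$mu[1]), exp(spec$mu[2]), exp(spec$mu[3]))
  expect_equal(coh$assessments$sld_cm, sld_at(p, coh$assessments$time_weeks))
  # identical kinetics imply identical progression scans
  expect_equal(length(unique(coh$survival$pfs_weeks)), 1L)
})

test_that("generation is reproducible under a fixed seed", {
  spec <- nsclc_arm_spec("docetaxel", n_patients = 50)
  c1 <- generate_cohort(spec, seed = 123)
  c2 <- generate_cohort(spec, seed = 123)
  expect_identical(c1$assessments, c2$assessments)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$params_true, c2$params_true)
  c3 <- generate_cohort(spec, seed = 124)
  expect_false(identical(c1$survival, c3$survival))
})

test_that("the docetaxel-like preset lands on its emulation targets", {
  coh <- generate_cohort(nsclc_arm_spec("docetaxel"), seed = 2026)
  s <- summarize_cohort(coh$assessments, coh$survival)
  expect_gt(s$median_baseline_sld, 8.3 - 2)
  expect_lt(s$median_baseline_sld, 8.3 + 2)
  expect_gt(s$km_pfs_months$median, 4.2 - 1.5)
  expect_lt(s$km_pfs_months$median, 4.2 + 1.5)
  d <- dropout_assessment(coh$survival)
  expect_lt(d$proportion, 0.10)
})

test_that("null post-progression model decouples kinetics from post-progression survival", {
  spec <- nsclc_arm_spec("docetaxel", n_patients = 2000, seed = 9,
                         censoring_time = 1e6)
  coh <- generate_cohort(spec)
  d <- merge(coh$params_true, coh$survival, by = "patient_id")
  d <- d[d$pfs_event == 1 & !d$progression_is_death, ]
  r <- cor(d$gr_true, d$os_weeks - d$pfs_weeks)
  expect_lt(abs(r), 0.05)
})

test_that("linked post-progression model induces the requested dependence", {
  spec <- nsclc_arm_spec("docetaxel", n_patients = 1500, seed = 10,
                         censoring_time = 1e6,
                         post_progression = list(model = "linked",
                                                 base_rate = log(2) / 30,
                                                 gamma_gr = 25,
                                                 gamma_ttg = 0))
  coh <- generate_cohort(spec)
  d <- merge(coh$params_true, coh$survival, by = "patient_id")
  d <- d[d$pfs_event == 1 & !d$progression_is_death, ]
  # faster-growing tumours now have shorter post-progression survival
  expect_lt(cor(log(d$gr_true), d$os_weeks - d$pfs_weeks, method = "spearman"),
            -0.15)
})

test_that("invalid specs fail before any sampling", {
  expect_error(cohort_spec(0, 8, 96, log(c(8, .06, .04)), c(.1, .1, .1), 0.3))
  expect_error(cohort_spec(10, 8, 96, log(c(8, .06, .04)), c(.1, .1, .1), 0.3,
                           progression_threshold = 0))
  expect_error(nsclc_arm_spec("docetaxel",
                              post_progression = list(model = "wrong")),
               "null|linked")
})
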