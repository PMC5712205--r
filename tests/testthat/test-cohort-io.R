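test_that("assessment and survival tables round-trip through CSV", {
  coh <- generate_cohort(nsclc_arm_spec("docetaxel", n_patients = 25), seed = 6)
  fa <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  write_assessments(coh$assessments, fa, seed = 6, config = coh$spec)
  write_survival(coh$survival, fs, seed = 6, config = coh$spec)

  a <- read_assessments(fa)
  s <- read_survival(fs)
  expect_equal(a$patient_id, coh$assessments$patient_id)
  expect_equal(a$sld_cm, round(coh$assessments$sld_cm, 4))
  expect_equal(s$pfs_weeks, round(coh$survival$pfs_weeks, 4))
  expect_equal(s$progression_is_death, coh$survival$progression_is_death)

  # header comments carry version, seed and config hash
  hdr <- readLines(fa, n = 3)
  expect_match(hdr[1], "^# tgmetrics")
  expect_match(hdr[2], "^# seed: 6$")
  expect_match(hdr[3], "^# config: md5 [0-9a-f]{32}$")

  # identical inputs give byte-identical outputs
  fa2 <- tempfile(fileext = ".csv")
  write_assessments(coh$assessments, fa2, seed = 6, config = coh$spec)
  expect_identical(readLines(fa), readLines(fa2))
  unlink(c(fa, fs, fa2))
})

test_that("malformed tables are rejected with row-numbered messages", {
  good <- data.frame(patient_id = c("p1", "p1", "p2"),
                     time_weeks = c(0, 8, 0), sld_cm = c(8, 7, 9))
  expect_silent(tgmetrics:::validate_assessments(good))

  dup <- rbind(good, data.frame(patient_id = "p1", time_weeks = 8, sld_cm = 6))
  expect_error(tgmetrics:::validate_assessments(dup), "duplicate.*4")
  neg <- good; neg$time_weeks[2] <- -1
  expect_error(tgmetrics:::validate_assessments(neg), "row\\(s\\): 2")
  zero <- good; zero$sld_cm[3] <- 0
  expect_error(tgmetrics:::validate_assessments(zero), "row\\(s\\): 3")
  expect_error(tgmetrics:::validate_assessments(good[, 1:2]), "missing column")

  sv <- data.frame(patient_id = "p1", pfs_weeks = 10, pfs_event = 2,
                   os_weeks = 20, os_event = 1)
  expect_error(tgmetrics:::validate_survival(sv), "0/1")
})

test_that("cohort summary computes the table-one style fields", {
  # single patient: baseline 10 cm, week-8 scan 8 cm -> -20% change
  a <- data.frame(patient_id = "p1", time_weeks = c(0, 8), sld_cm = c(10, 8))
  s <- data.frame(patient_id = "p1", pfs_weeks = 8, pfs_event = 1,
                  os_weeks = 30, os_event = 1, progression_is_death = FALSE)
  cs <- summarize_cohort(a, s)
  expect_equal(cs$median_pct_change_w6_10, -20)
  expect_equal(cs$median_baseline_sld, 10)
  expect_equal(cs$n_progression_events, 1)

  # no deaths: OS median missing, not zero
  s2 <- s; s2$os_event <- 0
  cs2 <- summarize_cohort(a, s2)
  expect_true(is.na(cs2$km_os_months$median))

  # no scan in the week 6-10 window: field missing, not zero
  a3 <- data.frame(patient_id = "p1", time_weeks = c(0, 16), sld_cm = c(10, 8))
  cs3 <- summarize_cohort(a3, s)
  expect_true(is.na(cs3$median_pct_change_w6_10))

  # all fields populated and finite on a generated arm
  coh <- generate_cohort(nsclc_arm_spec("docetaxel", n_patients = 120), seed = 8)
  cs4 <- summarize_cohort(coh$assessments, coh$survival)
  expect_true(is.finite(cs4$median_baseline_sld))
  expect_true(is.finite(cs4$median_pct_change_w6_10))
  expect_true(is.finite(cs4$km_pfs_months$median))
  expect_true(is.finite(cs4$km_os_minus_pfs_months$median))
  expect_lte(cs4$n_progressions_by_death, cs4$n_progression_events)
  expect_lte(cs4$n_progression_events, cs4$n_total)
})

test_that("drop-out assessment returns the death-progression proportion", {
  mk <- function(n_prog, n_death) {
    n <- n_prog + 5
    data.frame(patient_id = sprintf("p%03d", 1:n),
               pfs_weeks = rep(10, n),
               pfs_event = rep(c(1, 0), c(n_prog, 5)),
               os_weeks = rep(20, n), os_event = rep(1, n),
               progression_is_death = rep(c(TRUE, FALSE),
                                          c(n_death, n - n_death)))
  }
  d <- dropout_assessment(mk(10, 2))
  expect_equal(d$proportion, 0.2)
  expect_true(d$ci_low < 0.2 && 0.2 < d$ci_high)
  expect_equal(dropout_assessment(mk(10, 0))$proportion, 0)
  # the docetaxel-arm published split: 20 deaths among 353 progressions
  expect_equal(dropout_assessment(mk(353, 20))$proportion, 0.0567,
               tolerance = 1e-3)
  none <- mk(10, 0); none$pfs_event <- 0
  expect_error(dropout_assessment(none), "no progression")
})
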