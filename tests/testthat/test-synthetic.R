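test_that("generation is deterministic and satisfies all invariants", {
  a <- generate_cohort(cohort_spec(), seed = 1)
  b <- generate_cohort(cohort_spec(), seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 16)
  expect_equal(sum(a$vt_vf), 7)
  expect_true(all(a$qrs_ms < a$qt_ms))
  expect_silent(validate_cohort(a))

  c_ <- generate_cohort(cohort_spec(), seed = 2)
  expect_false(identical(a, c_))
})

test_that("synthetic records are internally Bazett-consistent", {
  for (seed in c(1, 5, 9)) {
    syn <- generate_cohort(cohort_spec(n_yes = 40, n_no = 40), seed = seed)
    audit <- audit_qtc_consistency(syn, formula = "bazett", tolerance_ms = 1)
    expect_false(any(audit$flagged))
  }
})

test_that("pathological specs fail cleanly", {
  # QTc range forces QT far outside its allowed band at low heart rates
  bad <- cohort_spec(qtc_mean_yes = 799, qtc_sd_yes = 0, hr_mean = 30, hr_sd = 0)
  expect_error(generate_cohort(bad, seed = 1), class = "qrsqtc_config_error")
  expect_error(cohort_spec(n_yes = -1), class = "qrsqtc_config_error")
  expect_error(cohort_spec(qrs_sd_yes = -2), class = "qrsqtc_config_error")
  expect_error(generate_cohort(cohort_spec(n_yes = 0, n_no = 0), seed = 1),
               class = "qrsqtc_config_error")
})

test_that("spec round-trips through JSON", {
  spec <- cohort_spec(n_yes = 11, hr_mean = 75, label_model = "logistic")
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(unclass(back), unclass(spec))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_yes": 5, "bogus_field": 1}', bad)
  expect_error(read_cohort_spec(bad), "bogus_field", class = "qrsqtc_config_error")
})

test_that("logistic labels track the ratio", {
  spec <- cohort_spec(n_yes = 300, n_no = 300, label_model = "logistic")
  syn <- generate_cohort(spec, seed = 4)
  r <- qrs_qtc_ratio(syn$qrs_ms, syn$qtc_ms, digits = NULL)
  # VT/VF should be much more common below the anchor midpoint (0.195)
  p_low <- mean(syn$vt_vf[r < 0.195])
  p_high <- mean(syn$vt_vf[r >= 0.195])
  expect_gt(p_low, 0.7)
  expect_lt(p_high, 0.3)
})

test_that("parameter recovery is accurate at n = 500 per group", {
  syn <- generate_cohort(cohort_spec(n_yes = 500, n_no = 500), seed = 7)
  rec <- recover_parameters(syn, ratio_digits = NULL)
  qtc_yes <- rec[rec$group == "vt_vf" & rec$variable == "qtc_ms", ]
  se <- 78 / sqrt(500)
  expect_lt(abs(qtc_yes$mean - 606), 3 * se)
  qrs_no <- rec[rec$group == "no_vt_vf" & rec$variable == "qrs_ms", ]
  expect_lt(abs(qrs_no$mean - 122), 3 * 23 / sqrt(500))
})

test_that("recovered SDs are within 5% of the generating values at n = 10^4", {
  syn <- generate_cohort(cohort_spec(n_yes = 1e4, n_no = 1e4), seed = 21)
  rec <- recover_parameters(syn, ratio_digits = NULL)
  g <- function(grp, v) rec$sd[rec$group == grp & rec$variable == v]
  expect_lt(abs(g("vt_vf", "qrs_ms") - 14) / 14, 0.05)
  expect_lt(abs(g("vt_vf", "qtc_ms") - 78) / 78, 0.05)
  expect_lt(abs(g("no_vt_vf", "qrs_ms") - 23) / 23, 0.05)
  expect_lt(abs(g("no_vt_vf", "qtc_ms") - 55) / 55, 0.05)
  expect_lt(abs(g("vt_vf", "hr_bpm") - 22) / 22, 0.05)
})

test_that("recovery on the packaged cohort gives the published descriptives", {
  rec <- recover_parameters(load_cohort())
  g <- function(grp, v, field) rec[[field]][rec$group == grp & rec$variable == v]
  expect_equal(round(g("vt_vf", "ratio", "mean"), 2), 0.15)
  expect_equal(round(g("no_vt_vf", "ratio", "mean"), 2), 0.24)
  expect_equal(round(g("vt_vf", "qrs_ms", "mean")), 90)
  expect_equal(round(g("vt_vf", "qrs_ms", "sd")), 14)
  expect_equal(round(g("no_vt_vf", "qtc_ms", "mean")), 508)
  expect_equal(round(g("no_vt_vf", "qtc_ms", "sd")), 55)
  expect_equal(round(g("vt_vf", "hr_bpm", "mean")), 85)
  expect_equal(round(g("no_vt_vf", "hr_bpm", "sd")), 25)
})

test_that("the ratio comparison is significant in almost all default cohorts", {
  sig <- vapply(1:200, function(s) {
    syn <- generate_cohort(cohort_spec(), seed = s)
    glance(compare_groups(syn, "ratio", ratio_digits = NULL))$significant
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("power at the published effect size and group sizes is near 1", {
  pw <- power_simulation(cohort_spec(), n_yes = 7, n_no = 9, alpha = 0.05,
                         reps = 1000, seed = 11)
  expect_gt(pw$power, 0.95)
  expect_identical(pw, power_simulation(cohort_spec(), n_yes = 7, n_no = 9,
                                        alpha = 0.05, reps = 1000, seed = 11))
  expect_error(power_simulation(cohort_spec(), reps = 50),
               class = "qrsqtc_domain_error")
})

test_that("power at alpha = 0 is zero", {
  pw <- power_simulation(cohort_spec(), alpha = 0, reps = 100, seed = 3)
  expect_equal(pw$power, 0)
})

test_that("the pipeline is calibrated under the null", {
  null_spec <- cohort_spec(qrs_mean_yes = 122, qrs_sd_yes = 23,
                           qtc_mean_yes = 508, qtc_sd_yes = 55)
  set.seed(99)
  pv <- vapply(1:2000, function(i) {
    syn <- generate_cohort(null_spec, seed = NULL)
    r <- qrs_qtc_ratio(syn$qrs_ms, syn$qtc_ms, digits = NULL)
    pooled_t_test(r[syn$vt_vf], r[!syn$vt_vf])$p_value
  }, numeric(1))
  # type-I error within the binomial 99% CI around alpha = 0.05
  expect_lt(abs(mean(pv < 0.05) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 2000))
  # p-values uniform on [0, 1]
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
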