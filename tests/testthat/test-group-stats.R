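test_that("population-SD descriptives reproduce the published group values", {
  cohort <- load_cohort()
  yes <- cohort$vt_vf

  qtc_yes <- describe_values(cohort$qtc_ms[yes])
  expect_equal(round(qtc_yes$mean), 606)
  expect_equal(round(qtc_yes$sd), 78)

  qrs_no <- describe_values(cohort$qrs_ms[!yes])
  expect_equal(round(qrs_no$mean), 122)
  expect_equal(round(qrs_no$sd), 23)

  # sample SD does not reproduce the published values
  expect_equal(round(describe_values(cohort$qtc_ms[yes], "sample")$sd), 85)

  expect_equal(describe_values(5)$mean, 5)
  expect_equal(describe_values(5)$sd, 0)
  expect_error(describe_values(numeric(0)), class = "qrsqtc_domain_error")
})

test_that("descriptives agree with the independent oracle on all groups", {
  cohort <- load_cohort()
  ratio <- cohort_ratio(cohort)
  for (v in list(ratio = ratio, qrs = cohort$qrs_ms,
                 qtc = cohort$qtc_ms, hr = cohort$hr_bpm)) {
    for (grp in list(v[cohort$vt_vf], v[!cohort$vt_vf])) {
      d <- describe_values(grp)
      expect_equal(d$mean, mean(grp))
      expect_equal(d$sd, pop_sd(grp))
    }
  }
})

test_that("Shapiro-Wilk passes on the cohort groups and rejects uniforms", {
  cohort <- load_cohort()
  ratio <- cohort_ratio(cohort)
  expect_gt(shapiro_wilk(ratio[cohort$vt_vf])$p_value, 0.05)
  expect_gt(shapiro_wilk(ratio[!cohort$vt_vf])$p_value, 0.05)
  set.seed(42)
  expect_lt(shapiro_wilk(runif(500))$p_value, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), class = "qrsqtc_domain_error")
})

test_that("Brown-Forsythe behaves as a median-centred Levene test", {
  cohort <- load_cohort()
  ratio <- cohort_ratio(cohort)
  bf <- brown_forsythe(ratio[cohort$vt_vf], ratio[!cohort$vt_vf])
  expect_gt(bf$p_value, 0.05)

  # cross-check against car's implementation
  skip_if_not_installed("car")
  lev <- car::leveneTest(
    ratio ~ factor(cohort$vt_vf), center = median,
    data = data.frame(ratio = ratio)
  )
  expect_equal(bf$statistic, lev[["F value"]][1])
  expect_equal(bf$p_value, lev[["Pr(>F)"]][1])
})

test_that("Brown-Forsythe detects unequal variances and degrades gracefully", {
  set.seed(7)
  a <- rnorm(50, 0, 1)
  b <- rnorm(50, 0, 5)
  expect_lt(brown_forsythe(a, b)$p_value, 0.05)

  same <- c(3, 3, 3)
  bf <- brown_forsythe(same, same)
  expect_equal(bf$statistic, 0)
  expect_equal(bf$p_value, 1)
  expect_error(brown_forsythe(1, c(1, 2)), class = "qrsqtc_domain_error")
})

test_that("pooled t-test matches stats::t.test and handles degenerate input", {
  set.seed(11)
  a <- rnorm(8, 1)
  b <- rnorm(12, 0)
  mine <- pooled_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$df, 18)
  expect_equal(mine$p_value, ref$p.value)

  same <- c(2, 2, 2)
  deg <- pooled_t_test(same, same)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(pooled_t_test(c(1, 1), c(2, 2)), class = "qrsqtc_domain_error")
})

test_that("two-tailed p is invariant to group order; t changes sign only", {
  cohort <- load_cohort()
  for (v in c("ratio", "qrs_ms", "qtc_ms", "hr_bpm")) {
    x <- if (v == "ratio") cohort_ratio(cohort) else cohort[[v]]
    ab <- pooled_t_test(x[cohort$vt_vf], x[!cohort$vt_vf])
    ba <- pooled_t_test(x[!cohort$vt_vf], x[cohort$vt_vf])
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$statistic, -ba$statistic)
  }
})

test_that("t-test agrees with the exact permutation oracle on the cohort", {
  cohort <- load_cohort()
  for (v in c("ratio", "qrs_ms", "qtc_ms", "hr_bpm")) {
    x <- if (v == "ratio") cohort_ratio(cohort) else cohort[[v]]
    p_t <- pooled_t_test(x[cohort$vt_vf], x[!cohort$vt_vf])$p_value
    p_perm <- perm_t_pvalue(x[cohort$vt_vf], x[!cohort$vt_vf])
    expect_lt(abs(p_t - p_perm), 0.01)
  }
})

test_that("compare_groups reproduces the published significance pattern", {
  cohort <- load_cohort()

  ratio <- glance(compare_groups(cohort, "ratio"))
  expect_true(ratio$significant)
  expect_lt(ratio$p_value, 0.0005)
  expect_equal(round(ratio$mean_yes, 2), 0.15)
  expect_equal(round(ratio$mean_no, 2), 0.24)
  expect_equal(ratio$df, 14L)

  qrs <- glance(compare_groups(cohort, "qrs_ms"))
  expect_true(qrs$significant)
  expect_lt(qrs$p_value, 0.01)

  qtc <- glance(compare_groups(cohort, "qtc_ms"))
  expect_true(qtc$significant)
  expect_lt(qtc$p_value, 0.05)

  hr <- glance(compare_groups(cohort, "hr_bpm"))
  expect_false(hr$significant)
  expect_gt(hr$p_value, 0.05)

  # variance homogeneity holds everywhere; normality holds in every group
  # except QTc among the non-VT/VF cases (Shapiro-Wilk p = 0.010), the one
  # place the recomputation departs from the reported blanket normality
  all_cmp <- compare_all_groups(cohort)
  expect_true(all(all_cmp$brown_forsythe_p > 0.05))
  expect_true(all(all_cmp$shapiro_p_yes > 0.05))
  expect_equal(all_cmp$variable[all_cmp$shapiro_p_no < 0.05], "qtc_ms")
  expect_equal(all_cmp$shapiro_p_no[all_cmp$variable == "qtc_ms"], 0.0102,
               tolerance = 0.01)
})

test_that("compare_groups rejects groups that are too small", {
  cohort <- load_cohort()
  tiny <- dplyr::bind_rows(
    filter_cohort(cohort, vt_vf)[1:2, ],
    filter_cohort(cohort, !vt_vf)
  )
  err <- expect_error(compare_groups(tiny, "ratio"),
                      class = "qrsqtc_domain_error")
  expect_match(conditionMessage(err), "vt_vf = TRUE")
})

test_that("tidy and glance give consistent views of a comparison", {
  cmp <- compare_groups(load_cohort(), "qrs_ms")
  td <- tidy(cmp)
  gl <- glance(cmp)
  expect_equal(nrow(td), 2)
  expect_equal(td$mean[td$group == "vt_vf"], gl$mean_yes)
  expect_equal(td$sd[td$group == "no_vt_vf"], gl$sd_no)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("boxplot_summary follows the linear-interpolation convention", {
  expect_equal(boxplot_summary(1:5)$median, 3)
  const <- boxplot_summary(rep(4.2, 10))
  expect_true(all(unlist(const) == 4.2))

  ratio_yes <- cohort_ratio(load_cohort())[load_cohort()$vt_vf]
  bs <- boxplot_summary(ratio_yes)
  q <- quantile(ratio_yes, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                names = FALSE)
  expect_equal(unlist(bs, use.names = FALSE), q[c(3, 2, 4, 1, 5)])
  expect_true(bs$p5 <= bs$p25 && bs$p25 <= bs$median &&
                bs$median <= bs$p75 && bs$p75 <= bs$p95)
  expect_error(boxplot_summary(numeric(0)), class = "qrsqtc_domain_error")
})
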