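test_that("packaged cohort matches the published case series", {
  cohort <- load_cohort()
  expect_equal(nrow(cohort), 16)
  expect_equal(sum(cohort$sex == "F"), 11)
  expect_equal(sum(cohort$sex == "M"), 5)
  expect_equal(sum(cohort$exposure_type == "intoxication"), 12)
  expect_equal(sum(cohort$exposure_type == "therapeutic"), 4)
  expect_equal(sum(cohort$vt_vf), 7)
  expect_equal(sum(cohort$substance == "escitalopram"), 3)
  expect_equal(sum(cohort$co_ingestants != ""), 12)
  # ECG columns match the published table row for row
  expect_equal(cohort$qrs_ms, published$qrs)
  expect_equal(cohort$qt_ms, published$qt)
  expect_equal(cohort$qtc_ms, published$qtc)
  expect_equal(cohort$hr_bpm, published$hr)
  expect_equal(cohort$vt_vf, published$vt_vf)
  expect_equal(cohort$age_years, published$age)
  expect_equal(cohort$dose_g, published$dose)
})

test_that("individual case values are as published", {
  cohort <- load_cohort()
  case5 <- cohort[cohort$case_id == 5, ]
  expect_equal(case5$qrs_ms, 85)
  expect_equal(case5$qtc_ms, 515)
  expect_equal(case5$hr_bpm, 93)
  expect_true(case5$vt_vf)
  # half-millisecond QRS fixes the column type as non-integer
  expect_equal(cohort$qrs_ms[cohort$case_id == 14], 92.5)
  # missing dose/serum are NA, never zero
  expect_true(is.na(cohort$dose_g[cohort$case_id == 6]))
  expect_true(all(is.na(cohort$dose_g) | cohort$dose_g > 0))
  expect_true(all(is.na(cohort$serum_ng_ml) | cohort$serum_ng_ml > 0))
})

test_that("cohort passes all range invariants", {
  cohort <- load_cohort()
  expect_true(all(cohort$qrs_ms >= 40 & cohort$qrs_ms <= 300))
  expect_true(all(cohort$qt_ms >= 200 & cohort$qt_ms <= 800))
  expect_true(all(cohort$qtc_ms >= 200 & cohort$qtc_ms <= 800))
  expect_true(all(cohort$hr_bpm >= 20 & cohort$hr_bpm <= 250))
  expect_true(all(cohort$qrs_ms < cohort$qt_ms))
  expect_false(anyDuplicated(cohort$case_id) > 0)
})

test_that("CSV and JSON round-trips are lossless including missingness", {
  cohort <- load_cohort()
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_cohort(cohort, csv)
  write_cohort(cohort, json, format = "json")
  expect_equal(as.data.frame(load_cohort(csv)), as.data.frame(cohort))
  expect_equal(as.data.frame(load_cohort(json)), as.data.frame(cohort))
  # JSON encodes missing dose as explicit null
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_length(raw, 16)
  expect_null(raw[[6]]$dose_g)
  expect_equal(raw[[14]]$qrs_ms, 92.5)
})

test_that("schema and validation errors name the problem", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("case_id,age_years", bad)
  expect_error(load_cohort(bad), "missing required column", class = "qrsqtc_schema_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_cohort(empty), class = "qrsqtc_schema_error")

  cohort <- load_cohort()
  cohort$qrs_ms[3] <- 500
  err <- expect_error(validate_cohort(cohort), class = "qrsqtc_validation_error")
  expect_match(conditionMessage(err), "case 3")
  expect_match(conditionMessage(err), "qrs_ms")

  cohort <- load_cohort()
  cohort$qt_ms[2] <- 100.5
  cohort$qt_ms[2] <- 150  # below the 200 ms floor
  expect_error(validate_cohort(cohort), "qt_ms", class = "qrsqtc_validation_error")

  cohort <- load_cohort()
  cohort$dose_g[1] <- 0
  expect_error(validate_cohort(cohort), "dose_g", class = "qrsqtc_validation_error")
})

test_that("filter_cohort preserves order and allows empty results", {
  cohort <- load_cohort()
  vt <- filter_cohort(cohort, vt_vf)
  expect_equal(nrow(vt), 7)
  expect_equal(vt$case_id, sort(vt$case_id))
  expect_equal(nrow(filter_cohort(cohort, substance == "escitalopram")), 3)
  expect_equal(nrow(filter_cohort(cohort, age_years > 200)), 0)
})
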