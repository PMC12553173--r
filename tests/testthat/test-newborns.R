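codes <- default_code_lists()

test_that("determine_dob requires cross-record agreement", {
  enr <- dplyr::bind_rows(
    make_enrollment("A", year = 2014, date_of_birth = D("2014-03-01")),
    make_enrollment("A", year = 2015, date_of_birth = D("2014-03-01")),
    make_enrollment("B", year = 2014, date_of_birth = D("2014-03-01")),
    make_enrollment("B", year = 2015, date_of_birth = D("2014-03-02")),
    make_enrollment("C", year = 2014, date_of_birth = as.Date(NA)),
    make_enrollment("D", year = 2014, date_of_birth = as.Date(NA)),
    make_enrollment("D", year = 2015, date_of_birth = D("2014-05-01"))
  )
  out <- determine_dob(enr)
  expect_equal(out$date_of_birth[out$beneficiary_id == "A"], D("2014-03-01"))
  expect_equal(out$dob_status[out$beneficiary_id == "B"], "conflict")
  expect_true(is.na(out$date_of_birth[out$beneficiary_id == "B"]))
  expect_equal(out$dob_status[out$beneficiary_id == "C"], "missing")
  # a single non-missing value alongside missings still determines the date
  expect_equal(out$dob_status[out$beneficiary_id == "D"], "ok")
})

test_that("newborn claims count up to 7 days post-birth, not before birth or after", {
  dob <- D("2015-04-10")
  enr <- make_enrollment(c("in7", "out8", "pre"), date_of_birth = dob)
  claims <- dplyr::bind_rows(
    make_claims("in7", dob + 7, code = "Z38.00"),
    make_claims("out8", dob + 8, code = "Z38.00"),
    make_claims("pre", dob - 1, code = "Z38.00")
  )
  out <- select_newborn_claims(claims, codes, determine_dob(enr))
  expect_equal(out$beneficiary_id, "in7")
})

test_that("coverage threshold is a strict 95% inequality", {
  nvss <- tibble::tibble(state = "WI", year = 2015L, medicaid_births = 1000L)
  mk <- function(n) tibble::tibble(state = "WI", year = 2015L, code_based_count = n)
  expect_true(compute_coverage(mk(940L), nvss)$fallback_active) # 0.94
  expect_false(compute_coverage(mk(950L), nvss)$fallback_active) # exactly 0.95
  cov <- compute_coverage(mk(1100L), nvss)
  expect_false(cov$fallback_active)
  expect_equal(cov$coverage_ratio, 1.10)
  # zero benchmark: undefined ratio, fallback active
  nvss0 <- tibble::tibble(state = "WI", year = 2015L, medicaid_births = 0L)
  cov0 <- compute_coverage(mk(0L), nvss0)
  expect_true(is.na(cov0$coverage_ratio))
  expect_true(cov0$fallback_active)
  # missing benchmark for a processed state-year is an error
  expect_error(
    compute_coverage(tibble::tibble(state = "MN", year = 2015L, code_based_count = 5L), nvss),
    "MN 2015"
  )
})

test_that("enrollment fallback takes enrollment up to one day after birth", {
  dob <- D("2015-06-01")
  enr <- make_enrollment(
    c("at1", "at2", "prenatal"),
    date_of_birth = dob,
    enrollment_start = c(dob + 1, dob + 2, dob - 30)
  )
  coverage <- tibble::tibble(
    state = "WI", year = 2015L, code_based_count = 0L, nvss_count = 10L,
    coverage_ratio = 0, fallback_active = TRUE
  )
  out <- enrollment_fallback(enr, determine_dob(enr), coverage)
  expect_setequal(out$beneficiary_id, c("at1", "prenatal"))
  # inactive fallback adds nobody
  coverage$fallback_active <- FALSE
  expect_equal(nrow(enrollment_fallback(enr, determine_dob(enr), coverage)), 0)
})

test_that("fallback excludes beneficiaries not born in the fallback state-year", {
  enr <- make_enrollment("older",
    year = 2015,
    date_of_birth = D("2010-06-01"), enrollment_start = D("2010-06-01")
  )
  coverage <- tibble::tibble(
    state = "WI", year = 2015L, code_based_count = 0L, nvss_count = 10L,
    coverage_ratio = 0, fallback_active = TRUE
  )
  expect_equal(nrow(enrollment_fallback(enr, determine_dob(enr), coverage)), 0)
})

test_that("sources partition: a candidate found both ways is code_based", {
  dob <- D("2015-02-01")
  enr <- make_enrollment("both", date_of_birth = dob, enrollment_start = dob)
  claims <- make_claims("both", dob, code = "Z38.00")
  nvss <- tibble::tibble(state = "WI", year = 2015L, medicaid_births = 100L)
  out <- identify_newborns(claims, enr, codes, nvss) # 1/100 => fallback active
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "code_based")
})

test_that("raising the coverage threshold never removes candidates (monotonicity)", {
  synth <- synth_generate(synth_config(seed = 13))
  ids <- function(threshold) {
    out <- identify_newborns(
      synth$claims, synth$enrollment, synth$code_lists, synth$nvss,
      pipeline_config(coverage_threshold = threshold)
    )
    out$infant_id
  }
  lo <- ids(0.5)
  mid <- ids(0.95)
  hi <- ids(1.5)
  expect_true(all(lo %in% mid))
  expect_true(all(mid %in% hi))
  # code-based candidates do not depend on the threshold
  out_lo <- identify_newborns(
    synth$claims, synth$enrollment, synth$code_lists, synth$nvss,
    pipeline_config(coverage_threshold = 0.5)
  )
  out_hi <- identify_newborns(
    synth$claims, synth$enrollment, synth$code_lists, synth$nvss,
    pipeline_config(coverage_threshold = 1.5)
  )
  expect_setequal(
    out_lo$infant_id[out_lo$source == "code_based"],
    out_hi$infant_id[out_hi$source == "code_based"]
  )
})

test_that("a fully mother-billed state yields zero code-based newborns and fallback recovers them", {
  cfg <- synth_config(
    states = tibble::tibble(
      state = "SC", n_mothers = 150L, has_case_ids = TRUE,
      newborn_billed_under_mother_prob = 1, code_coverage = 1
    ),
    newborn_without_medicaid_delivery_rate = 0,
    late_enrollment_rate = 0, twin_rate = 0,
    missingness = c(
      residential_zip = 0, facility_zip = 0, race_ethnicity = 0, case_id = 0
    ),
    seed = 4
  )
  synth <- synth_generate(cfg)
  out <- identify_newborns(synth$claims, synth$enrollment, synth$code_lists, synth$nvss)
  coverage <- attr(out, "coverage")
  expect_true(all(coverage$code_based_count == 0))
  expect_true(all(coverage$fallback_active))
  expect_true(all(out$source == "enrollment_based"))
  # all enrolled-at-birth infants recovered
  expect_setequal(out$infant_id, synth$truth$infant_id)
})

test_that("multiple-gestation newborns are flagged from post-birth claims", {
  dob <- D("2015-02-01")
  enr <- make_enrollment(c("twin", "single"), date_of_birth = dob, enrollment_start = dob)
  claims <- dplyr::bind_rows(
    make_claims("twin", dob, code = "Z38.00"),
    make_claims("twin", dob, code = "Z38.30"),
    make_claims("single", dob, code = "Z38.00")
  )
  nvss <- tibble::tibble(state = "WI", year = 2015L, medicaid_births = 2L)
  out <- identify_newborns(claims, enr, codes, nvss)
  expect_true(out$multiple_gestation[out$infant_id == "twin"])
  expect_equal(out$excluded_reason[out$infant_id == "twin"], "multiple_gestation")
  expect_false(out$multiple_gestation[out$infant_id == "single"])
})

test_that("newborn-coded beneficiaries without a confident DOB are excluded with reason", {
  enr <- dplyr::bind_rows(
    make_enrollment("conflict", year = 2014, date_of_birth = D("2015-02-01")),
    make_enrollment("conflict", year = 2015, date_of_birth = D("2015-02-02"))
  )
  claims <- make_claims("conflict", D("2015-02-01"), code = "Z38.00")
  nvss <- tibble::tibble(state = "WI", year = c(2014L, 2015L), medicaid_births = 5L)
  out <- identify_newborns(claims, enr, codes, nvss)
  expect_equal(out$excluded_reason, "no_confident_dob")
  expect_true(is.na(out$date_of_birth))
})
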