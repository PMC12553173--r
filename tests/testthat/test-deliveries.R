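codes <- default_code_lists()

test_that("age filter is inclusive at 12 and 50, birthday-based", {
  enr <- make_enrollment("A", date_of_birth = D("2000-01-01"))
  claims <- make_claims("A", c(D("2011-12-31"), D("2012-01-01")))
  out <- select_delivery_claims(claims, codes, enr)
  expect_equal(out$service_date, D("2012-01-01")) # age 11 excluded, 12 retained
  expect_equal(out$age_at_claim, 12)

  enr50 <- make_enrollment("B", date_of_birth = D("1965-06-15"))
  claims50 <- make_claims("B", c(D("2015-06-14"), D("2015-06-15"), D("2016-06-15")))
  out50 <- select_delivery_claims(claims50, codes, enr50)
  # ages 49, 50, 51: the 51st-birthday claim drops
  expect_equal(out50$service_date, c(D("2015-06-14"), D("2015-06-15")))
})

test_that("claims without delivery codes and beneficiaries without DOB are excluded", {
  enr <- dplyr::bind_rows(
    make_enrollment("A"),
    make_enrollment("NoDob", date_of_birth = as.Date(NA))
  )
  claims <- dplyr::bind_rows(
    make_claims("A", 0),
    make_claims("A", 0, code = "Z99", code_system = "ICD10-DX"),
    make_claims("NoDob", 0)
  )
  out <- select_delivery_claims(claims, codes, enr)
  expect_equal(nrow(out), 1)
  excl <- attr(out, "exclusions")
  expect_equal(excl$beneficiaries_missing_dob, 1)
})

test_that("claims merge below the 270-day midpoint gap and split at or above it", {
  base <- D("2014-01-01")
  expect_equal(cluster_claim_dates(base + c(0, 100)), c(1L, 1L))
  expect_equal(cluster_claim_dates(base + c(0, 300)), c(1L, 2L))
  expect_equal(cluster_claim_dates(base + c(0, 269)), c(1L, 1L))
  expect_equal(cluster_claim_dates(base + c(0, 270)), c(1L, 2L))
  # merges recompute midpoints: 0,2 merge (mid 1), then 265 joins (mid 132),
  # leaving 530 at gap 398 >= 270
  expect_equal(cluster_claim_dates(base + c(0, 2, 265, 530)), c(1L, 1L, 1L, 2L))
  expect_equal(cluster_claim_dates(as.Date(character())), integer(0))
})

test_that("clustering equals the exhaustive greedy oracle and emits valid partitions", {
  base <- D("2013-06-01")
  for (seed in 1:30) {
    dates <- withr::with_seed(seed, base + sort(sample(0:900, sample(2:6, 1))))
    got <- cluster_claim_dates(dates)
    expect_equal(got, cluster_oracle(dates), info = paste("seed", seed))
    part <- split(seq_along(dates), got)
    expect_true(partition_valid(as.numeric(dates), part),
      info = paste("seed", seed)
    )
    # valid partition exists among all contiguous partitions (sanity on oracle)
    valid <- Filter(
      function(p) partition_valid(as.numeric(dates), p),
      contiguous_partitions(length(dates))
    )
    expect_gte(length(valid), 1)
  }
})

test_that("clustering is invariant to claim order", {
  dates <- D("2012-01-01") + c(400, 0, 3, 402, 800, 1)
  ids <- cluster_claim_dates(dates)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(cluster_claim_dates(dates[perm]), ids[perm])
})

test_that("window spans of 7 days are retained and 8 are excluded", {
  enr <- make_enrollment(c("A", "B"))
  claims <- dplyr::bind_rows(
    make_claims("A", c(0, 7)),
    make_claims("B", c(0, 8))
  )
  out <- identify_deliveries(claims, enr, codes)
  a <- out[out$mother_id == "A", ]
  b <- out[out$mother_id == "B", ]
  expect_equal(a$excluded_reason, "none")
  expect_equal(a$span_days, 7)
  expect_equal(b$excluded_reason, "wide_window")
  # single-day delivery: degenerate window retained
  single <- identify_deliveries(make_claims("A", 0), enr, codes)
  expect_equal(single$window_start, single$window_end)
  expect_equal(single$excluded_reason, "none")
})

test_that("the inclusive-count window convention is switchable", {
  enr <- make_enrollment("A")
  claims <- make_claims("A", c(0, 7))
  cfg <- pipeline_config(window_span_counts_days = TRUE)
  out <- identify_deliveries(claims, enr, codes, cfg)
  expect_equal(out$span_days, 8)
  expect_equal(out$excluded_reason, "wide_window")
})

test_that("multiple-gestation codes in the cluster window flag the delivery", {
  enr <- make_enrollment(c("A", "B"))
  claims <- dplyr::bind_rows(
    make_claims("A", c(0, 1)),
    make_claims("A", 1, code = "O30.003", code_system = "ICD10-DX"),
    make_claims("B", c(0, 1))
  )
  out <- identify_deliveries(claims, enr, codes)
  expect_equal(out$multiple_gestation[out$mother_id == "A"], TRUE)
  expect_equal(out$excluded_reason[out$mother_id == "A"], "multiple_gestation")
  expect_equal(out$multiple_gestation[out$mother_id == "B"], FALSE)

  # empty multiple-gestation list: never flagged
  no_mg <- dplyr::filter(codes, role != "multiple_gestation")
  out2 <- identify_deliveries(claims, enr, no_mg)
  expect_false(any(out2$multiple_gestation))
})

test_that("every delivery's midpoint gap invariant and claim conservation hold", {
  synth <- synth_generate(synth_config(seed = 21))
  deliveries <- identify_deliveries(synth$claims, synth$enrollment, synth$code_lists)
  gaps_ok <- deliveries |>
    dplyr::group_by(mother_id) |>
    dplyr::summarise(
      ok = dplyr::n() < 2 || min(diff(sort(as.numeric(midpoint)))) >= 270
    )
  expect_true(all(gaps_ok$ok))
  # claim conservation: each selected delivery claim date in exactly one event
  sel <- select_delivery_claims(synth$claims, synth$code_lists, synth$enrollment)
  membership <- sel |>
    dplyr::distinct(beneficiary_id, service_date) |>
    dplyr::left_join(
      tidyr::unnest(
        dplyr::select(deliveries, mother_id, delivery_id, claim_dates),
        claim_dates
      ),
      by = c(beneficiary_id = "mother_id", service_date = "claim_dates")
    ) |>
    dplyr::count(beneficiary_id, service_date)
  expect_true(all(membership$n == 1))
  # windows contain all claim dates; midpoints are floor of the span middle
  expect_true(all(purrr::pmap_lgl(
    deliveries[, c("claim_dates", "window_start", "window_end", "midpoint")],
    function(claim_dates, window_start, window_end, midpoint) {
      all(claim_dates >= window_start) && all(claim_dates <= window_end) &&
        midpoint == window_start + floor(as.numeric(window_end - window_start) / 2)
    }
  )))
})

test_that("identify_deliveries is invariant to claim row order", {
  synth <- synth_generate(synth_config(seed = 8))
  d1 <- identify_deliveries(synth$claims, synth$enrollment, synth$code_lists)
  shuffled <- withr::with_seed(1, synth$claims[sample(nrow(synth$claims)), ])
  d2 <- identify_deliveries(shuffled, synth$enrollment, synth$code_lists)
  expect_equal(
    dplyr::arrange(d1, delivery_id), dplyr::arrange(d2, delivery_id),
    ignore_attr = TRUE
  )
})
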