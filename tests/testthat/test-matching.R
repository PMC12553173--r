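test_that("the default schedule has 6 phases x 8 steps with the documented structure", {
  s <- phase_schedule()
  expect_equal(nrow(s), 48)
  expect_equal(unique(s$phase), 1:6)
  expect_equal(s$date_tolerance[s$step == 1], c(0, 1, 2, 0, 1, 2))
  expect_equal(s$case_id_required[s$step == 1], c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(
    vapply(s$vars[s$phase == 1], length, integer(1)),
    c(3L, 2L, 2L, 2L, 1L, 1L, 1L, 0L)
  )
})

test_that("date tolerance widens the window symmetrically", {
  d <- make_delivery_pool("D1", D("2015-06-01"), D("2015-06-03"))
  after <- make_newborn_pool("N1", D("2015-06-04"))
  before <- make_newborn_pool("N2", D("2015-05-31"))
  expect_equal(nrow(candidate_pairs(d, after, date_tolerance = 0)), 0)
  expect_equal(nrow(candidate_pairs(d, after, date_tolerance = 1)), 1)
  expect_equal(nrow(candidate_pairs(d, before, date_tolerance = 0)), 0)
  expect_equal(nrow(candidate_pairs(d, before, date_tolerance = 1)), 1)
})

test_that("required variables must be present on both sides and equal", {
  d <- make_delivery_pool("D1", D("2015-06-01"), case_id = "H1")
  n_full <- make_newborn_pool("N1", D("2015-06-01"), case_id = "H1")
  n_missing_zip <- dplyr::mutate(n_full, residential_zip = NA_character_)
  n_other_state <- dplyr::mutate(n_full, state = "MN")
  vars3 <- c("residential_zip", "facility_zip", "race_ethnicity")
  expect_equal(nrow(candidate_pairs(d, n_full, 0, TRUE, vars3)), 1)
  expect_equal(nrow(candidate_pairs(d, n_missing_zip, 0, TRUE, vars3)), 0)
  # missing never wildcards, but dropping the requirement readmits the pair
  expect_equal(nrow(candidate_pairs(d, n_missing_zip, 0, TRUE, c("facility_zip", "race_ethnicity"))), 1)
  expect_equal(nrow(candidate_pairs(d, n_other_state, 0, TRUE, vars3)), 0)
  # case-id requirement needs presence on both sides
  d_nocid <- dplyr::mutate(d, case_id = NA_character_)
  expect_equal(nrow(candidate_pairs(d_nocid, n_full, 0, TRUE, character(0))), 0)
  expect_equal(nrow(candidate_pairs(d_nocid, n_full, 0, FALSE, character(0))), 1)
})

test_that("only mutually unique pairs are accepted", {
  pairs <- tibble::tibble(
    delivery_id = c("D1", "D1", "D2"),
    mother_id = c("M1", "M1", "M2"),
    infant_id = c("N1", "N2", "N2"),
    state = "WI"
  )
  expect_equal(nrow(accept_unique(pairs)), 0) # D1 degree 2, N2 degree 2
  expect_equal(nrow(accept_unique(pairs[c(1, 3), ])), 2)
  expect_equal(accept_unique(pairs[1, ])$infant_id, "N1")
})

test_that("matching an empty newborn pool yields zero links and zero tallies", {
  d <- make_delivery_pool("D1", D("2015-06-01"))
  n <- make_newborn_pool(character(0), as.Date(character()))
  fit <- run_matching(d, n)
  expect_equal(nrow(fit$links), 0)
  expect_true(all(fit$tallies$n_links == 0))
  expect_equal(nrow(fit$tallies), 48)
})

test_that("two indistinguishable deliveries and newborns never link in any cell", {
  d <- make_delivery_pool(c("D1", "D2"), D("2015-06-01"), case_id = "H1")
  n <- make_newborn_pool(c("N1", "N2"), D("2015-06-01"), case_id = "H1")
  fit <- run_matching(d, n)
  expect_equal(nrow(fit$links), 0)
  expect_true(all(fit$tallies$n_links == 0))
  # brute force agrees
  expect_equal(nrow(brute_force_match(d, n)), 0)
})

test_that("a unique pair links in phase 1 step 1 with full agreement", {
  d <- make_delivery_pool("D1", D("2015-06-01"), case_id = "H1")
  n <- make_newborn_pool("N1", D("2015-06-01"), case_id = "H1")
  fit <- run_matching(d, n)
  expect_equal(nrow(fit$links), 1)
  expect_equal(fit$links$phase, 1L)
  expect_equal(fit$links$step, 1L)
  expect_equal(fit$links$matched_on, "residential_zip+facility_zip+race_ethnicity")
})

test_that("missing case IDs postpone links to the case-ID-free phases", {
  d <- make_delivery_pool("D1", D("2015-06-01"), case_id = NA_character_)
  n <- make_newborn_pool("N1", D("2015-06-01"), case_id = NA_character_)
  fit <- run_matching(d, n)
  expect_equal(fit$links$phase, 4L)
})

test_that("excluded records never enter the pools", {
  d <- make_delivery_pool(c("D1", "D2"), D("2015-06-01"), case_id = c("H1", "H2")) |>
    dplyr::mutate(excluded_reason = c("none", "multiple_gestation"))
  n <- make_newborn_pool(c("N1", "N2"), D("2015-06-01"), case_id = c("H1", "H2")) |>
    dplyr::mutate(excluded_reason = c("none", "no_confident_dob"))
  fit <- run_matching(d, n)
  expect_equal(fit$links$delivery_id, "D1")
  expect_equal(fit$pools$n_deliveries, 1)
  expect_equal(fit$pools$n_newborns, 1)
})

test_that("emitted links always satisfy the hard constraints", {
  for (seed in c(2, 9)) {
    pools <- make_random_pools(seed)
    fit <- run_matching(pools$deliveries, pools$newborns)
    checked <- fit$links |>
      dplyr::select(delivery_id, infant_id, phase, step) |>
      dplyr::inner_join(
        dplyr::select(pools$deliveries, delivery_id,
          state_d = state, window_start, window_end
        ),
        by = "delivery_id"
      ) |>
      dplyr::inner_join(
        dplyr::select(pools$newborns, infant_id, state_n = state, date_of_birth),
        by = "infant_id"
      ) |>
      dplyr::inner_join(phase_schedule()[, c("phase", "step", "date_tolerance")],
        by = c("phase", "step")
      )
    expect_true(all(checked$state_d == checked$state_n))
    expect_true(all(
      checked$date_of_birth >= checked$window_start - checked$date_tolerance &
        checked$date_of_birth <= checked$window_end + checked$date_tolerance
    ))
    expect_equal(anyDuplicated(fit$links$delivery_id), 0)
    expect_equal(anyDuplicated(fit$links$infant_id), 0)
  }
})

test_that("matching is invariant to input row order", {
  pools <- make_random_pools(5)
  fit1 <- run_matching(pools$deliveries, pools$newborns)
  fit2 <- withr::with_seed(99, run_matching(
    pools$deliveries[sample(nrow(pools$deliveries)), ],
    pools$newborns[sample(nrow(pools$newborns)), ]
  ))
  expect_equal(sort_links(fit1$links), sort_links(fit2$links))
  expect_equal(fit1$tallies$n_links, fit2$tallies$n_links)
})

test_that("blocked matcher equals the exhaustive reference on random pools", {
  phases_seen <- integer(0)
  for (seed in 1:8) {
    pools <- make_random_pools(seed, n_d = 50, n_n = 60)
    fit <- run_matching(pools$deliveries, pools$newborns)
    oracle <- brute_force_match(pools$deliveries, pools$newborns)
    expect_equal(sort_links(fit$links), sort_links(oracle), info = paste("seed", seed))
    phases_seen <- union(phases_seen, fit$links$phase)
  }
  expect_gte(length(phases_seen), 4)
})

test_that("the matcher and reference agree in within-step fixed-point mode", {
  cfg <- pipeline_config(iterate_within_step = TRUE)
  for (seed in 3:5) {
    pools <- make_random_pools(seed)
    fit <- run_matching(pools$deliveries, pools$newborns, cfg)
    oracle <- brute_force_match(pools$deliveries, pools$newborns, cfg)
    expect_equal(sort_links(fit$links), sort_links(oracle), info = paste("seed", seed))
    # fixed-point mode can only add links relative to single-pass mode
    single <- run_matching(pools$deliveries, pools$newborns)
    expect_gte(nrow(fit$links), nrow(single$links))
  }
})

test_that("cumulative link counts are non-decreasing and greedy-prefix-consistent", {
  pools <- make_random_pools(7)
  fit <- run_matching(pools$deliveries, pools$newborns)
  expect_true(all(diff(fit$tallies$cum_links) >= 0))
  # running a schedule prefix alone reproduces the prefix of the full run
  prefix <- phase_schedule()[1:16, ] # phases 1-2
  fit_prefix <- run_matching(pools$deliveries, pools$newborns, schedule = prefix)
  expect_equal(
    sort_links(fit_prefix$links),
    sort_links(dplyr::filter(fit$links, phase <= 2))
  )
})

test_that("tidy and glance summarize a matching run", {
  pools <- make_random_pools(1)
  fit <- run_matching(pools$deliveries, pools$newborns)
  expect_identical(tidy(fit), fit$links)
  g <- glance(fit)
  expect_equal(g$n_dyads, nrow(fit$links))
  expect_equal(
    g$pct_deliveries_linked,
    100 * nrow(fit$links) / nrow(pools$deliveries)
  )
  expect_output(print(fit), "dyad_matching")
})
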