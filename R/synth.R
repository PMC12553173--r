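#' Synthetic-data generator configuration
#'
#' Defines the study conditions the generator emulates: multi-state claims
#' with the reporting heterogeneity documented for Medicaid — states that do
#' not assign household case IDs, states where newborn care is billed under
#' the mother's coverage (making code-based newborn detection fail), partial
#' delivery/newborn code coverage, per-variable missingness, claim-date
#' jitter, newborns whose mothers' deliveries were not Medicaid-paid, and
#' payer misreporting in the vital-statistics benchmark.
#'
#' @param states Per-state settings: a tibble with columns `state`,
#'   `n_mothers`, `has_case_ids`, `newborn_billed_under_mother_prob`,
#'   `code_coverage`.
#' @param years Integer study years; all births fall in these years.
#' @param second_delivery_prob Probability a mother has a second delivery.
#' @param interbirth_gap_range Two integers, the uniform range (days) between
#'   a mother's consecutive delivery dates; the minimum must be at least 280
#'   so distinct true deliveries remain separable by the 270-day clustering
#'   gap.
#' @param twin_rate Probability a delivery is a twin (multiple-gestation)
#'   birth.
#' @param missingness Named fractions in `[0, 1]` for `residential_zip`,
#'   `facility_zip`, `race_ethnicity`, `case_id`: each value/NPI is
#'   independently masked at this rate.
#' @param claim_date_jitter Maximum days after the delivery date at which
#'   additional delivery claims are filed (uniform on `0:claim_date_jitter`).
#' @param infant_race_agreement Probability an infant's recorded
#'   race/ethnicity equals the mother's; otherwise it is recorded as
#'   `Unknown/Other`, reflecting the sparser race recording of newborn
#'   enrollment records.
#' @param newborn_without_medicaid_delivery_rate Fraction of additional
#'   newborns enrolled at birth whose mothers have no Medicaid delivery.
#' @param late_enrollment_rate Fraction of infants whose enrollment starts
#'   more than one day after birth (they evade the enrollment fallback).
#' @param nvss_payer_misreport_rate Probability a true Medicaid birth is not
#'   recorded as Medicaid-payer in the benchmark counts.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param race_distribution Named probabilities over the reporting
#'   race/ethnicity categories used for mothers (normalized internally).
#' @param code_lists Code lists used on generated claims (default the
#'   illustrative built-in lists).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(states = tibble::tibble(
                           state = c("WI", "TX", "SC"),
                           n_mothers = c(400L, 400L, 400L),
                           has_case_ids = c(TRUE, FALSE, TRUE),
                           newborn_billed_under_mother_prob = c(0.05, 0.10, 0.90),
                           code_coverage = c(0.98, 0.95, 0.95)
                         ),
                         years = 2014:2016,
                         second_delivery_prob = 0.25,
                         interbirth_gap_range = c(300L, 700L),
                         twin_rate = 0.015,
                         missingness = c(
                           residential_zip = 0.05, facility_zip = 0.05,
                           race_ethnicity = 0.10, case_id = 0.02
                         ),
                         claim_date_jitter = 2L,
                         infant_race_agreement = 0.8,
                         newborn_without_medicaid_delivery_rate = 0.10,
                         late_enrollment_rate = 0.02,
                         nvss_payer_misreport_rate = 0.05,
                         seed = 1L,
                         race_distribution = default_race_distribution(),
                         code_lists = default_code_lists()) {
  assert_columns(states, c(
    "state", "n_mothers", "has_case_ids",
    "newborn_billed_under_mother_prob", "code_coverage"
  ), "states")
  fr <- c(
    second_delivery_prob, twin_rate, missingness, infant_race_agreement,
    newborn_without_medicaid_delivery_rate, late_enrollment_rate,
    nvss_payer_misreport_rate,
    states$newborn_billed_under_mother_prob, states$code_coverage
  )
  if (any(fr < 0 | fr > 1)) {
    stop("all rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  need <- c("residential_zip", "facility_zip", "race_ethnicity", "case_id")
  if (!all(need %in% names(missingness))) {
    stop("missingness must name all four matching variables", call. = FALSE)
  }
  if (interbirth_gap_range[1] < 280) {
    stop(
      "interbirth_gap_range minimum must be >= 280 days; ",
      "closer deliveries would not be separable by the 270-day clustering gap",
      call. = FALSE
    )
  }
  if (claim_date_jitter < 0) stop("claim_date_jitter must be non-negative", call. = FALSE)
  if (!all(names(race_distribution) %in% race_levels()) ||
    length(race_distribution) == 0 || any(race_distribution < 0)) {
    stop("race_distribution must be non-negative probabilities over the reporting categories",
      call. = FALSE
    )
  }
  structure(
    list(
      states = states, years = as.integer(years),
      second_delivery_prob = second_delivery_prob,
      interbirth_gap_range = as.integer(interbirth_gap_range),
      twin_rate = twin_rate, missingness = missingness,
      claim_date_jitter = as.integer(claim_date_jitter),
      infant_race_agreement = infant_race_agreement,
      newborn_without_medicaid_delivery_rate = newborn_without_medicaid_delivery_rate,
      late_enrollment_rate = late_enrollment_rate,
      nvss_payer_misreport_rate = nvss_payer_misreport_rate,
      seed = as.integer(seed),
      race_distribution = race_distribution / sum(race_distribution),
      code_lists = code_lists
    ),
    class = "synth_config"
  )
}

#' Default race/ethnicity distribution of generated mothers
#'
#' Approximates the published demographic mix of Medicaid deliveries across
#' the eight reporting categories.
#'
#' @return A named numeric vector of probabilities.
#' @export
default_race_distribution <- function() {
  setNames(
    c(0.38, 0.26, 0.21, 0.031, 0.016, 0.007, 0.030, 0.066),
    race_levels()
  )
}

sample_codes <- function(code_lists, role, n) {
  pool <- code_lists[code_lists$role == role, , drop = FALSE]
  i <- sample.int(nrow(pool), n, replace = TRUE)
  pool[i, c("code", "system")]
}

gen_state <- function(srow, state_idx, cfg) {
  n <- srow$n_mothers
  state <- srow$state
  date_lo <- as.Date(sprintf("%d-01-01", min(cfg$years)))
  date_hi <- as.Date(sprintf("%d-12-01", max(cfg$years)))
  span <- as.integer(date_hi - date_lo)

  n_zip <- max(3L, ceiling(n / 15))
  zips <- sprintf("%05d", sample(10000:99899, n_zip))
  n_fac <- max(2L, ceiling(n / 150))
  fac <- tibble::tibble(
    npi = sprintf("%03d%07d", state_idx, seq_len(n_fac)),
    zip = sprintf("%05d", sample(10000:99899, n_fac))
  )

  mothers <- tibble::tibble(
    mother_id = sprintf("%s-M%05d", state, seq_len(n)),
    residential_zip = sample(zips, n, replace = TRUE),
    race = sample(names(cfg$race_distribution), n, replace = TRUE, prob = cfg$race_distribution),
    case_id = if (srow$has_case_ids) {
      sprintf("%s-H%05d", state, seq_len(n))
    } else {
      NA_character_
    },
    d1 = date_lo + sample.int(span + 1, n, replace = TRUE) - 1L
  )
  mothers$mother_dob <- mothers$d1 -
    round(stats::runif(n, min = 16, max = 43) * 365.25)

  gap <- sample(
    seq(cfg$interbirth_gap_range[1], cfg$interbirth_gap_range[2]),
    n,
    replace = TRUE
  )
  second <- stats::runif(n) < cfg$second_delivery_prob &
    mothers$d1 + gap <= date_hi
  deliveries <- dplyr::bind_rows(
    dplyr::mutate(mothers, delivery_date = .data$d1, parity = 1L),
    dplyr::mutate(mothers[second, ], delivery_date = .data$d1 + gap[second], parity = 2L)
  ) |>
    dplyr::select(-"d1") |>
    dplyr::arrange(.data$mother_id, .data$parity)
  nd <- nrow(deliveries)
  deliveries$twin <- stats::runif(nd) < cfg$twin_rate
  deliveries$fac_i <- sample.int(n_fac, nd, replace = TRUE)
  deliveries$delivery_key <- sprintf("%s-T%05d", state, seq_len(nd))

  # delivery claims: first claim on the delivery date, extras jittered after it
  n_claims <- sample.int(3L, nd, replace = TRUE)
  dcl <- deliveries[rep(seq_len(nd), n_claims), ]
  first <- !duplicated(dcl$delivery_key)
  offs <- ifelse(
    first, 0L,
    sample.int(cfg$claim_date_jitter + 1L, nrow(dcl), replace = TRUE) - 1L
  )
  dcodes <- sample_codes(cfg$code_lists, "delivery", nrow(dcl))
  delivery_claims <- tibble::tibble(
    beneficiary_id = dcl$mother_id, state = state,
    service_date = dcl$delivery_date + offs,
    code = dcodes$code, code_system = dcodes$system,
    provider_npi = fac$npi[dcl$fac_i], source_file = "inpatient"
  )
  mg <- cfg$code_lists[cfg$code_lists$role == "multiple_gestation", ][1, ]
  twin_claims <- deliveries[deliveries$twin, ]
  mg_claims <- tibble::tibble(
    beneficiary_id = twin_claims$mother_id, state = state,
    service_date = twin_claims$delivery_date,
    code = mg$code, code_system = mg$system,
    provider_npi = fac$npi[twin_claims$fac_i], source_file = "inpatient"
  )

  # infants: one per delivery, two for twins
  inf <- deliveries[rep(seq_len(nd), 1L + deliveries$twin), ]
  ni <- nrow(inf)
  inf$infant_id <- sprintf("%s-I%06d", state, seq_len(ni))
  inf$dob <- inf$delivery_date
  inf$sex <- sample(c("F", "M"), ni, replace = TRUE)
  keep_race <- stats::runif(ni) < cfg$infant_race_agreement
  inf$race_i <- ifelse(keep_race, inf$race, "Unknown/Other")
  late <- stats::runif(ni) < cfg$late_enrollment_rate
  inf$enrollment_start <- inf$dob +
    ifelse(late, sample(2:30, ni, replace = TRUE), sample(0:1, ni, replace = TRUE))
  billed_under_mother <- stats::runif(ni) < srow$newborn_billed_under_mother_prob
  covered <- stats::runif(ni) < srow$code_coverage
  inf$own_claims <- !billed_under_mother & covered

  nb_bene <- ifelse(inf$own_claims, inf$infant_id, inf$mother_id)
  nb_n <- 1L + (stats::runif(ni) < 0.5)
  nbl <- inf[rep(seq_len(ni), nb_n), ]
  nb_bene_l <- nb_bene[rep(seq_len(ni), nb_n)]
  nb_off <- sample(0:2, nrow(nbl), replace = TRUE)
  ncodes <- sample_codes(cfg$code_lists, "newborn_care", nrow(nbl))
  newborn_claims <- tibble::tibble(
    beneficiary_id = nb_bene_l, state = state,
    service_date = nbl$dob + nb_off,
    code = ncodes$code, code_system = ncodes$system,
    provider_npi = fac$npi[nbl$fac_i], source_file = "other_services"
  )
  twin_inf <- inf[inf$twin & inf$own_claims, ]
  mg_inf_claims <- tibble::tibble(
    beneficiary_id = twin_inf$infant_id, state = state,
    service_date = twin_inf$dob,
    code = mg$code, code_system = mg$system,
    provider_npi = fac$npi[twin_inf$fac_i], source_file = "other_services"
  )

  # newborns whose mothers had no Medicaid-paid delivery
  nx <- round(cfg$newborn_without_medicaid_delivery_rate * ni)
  extra <- tibble::tibble(
    infant_id = sprintf("%s-X%05d", state, seq_len(nx)),
    dob = date_lo + sample.int(span + 1, nx, replace = TRUE) - 1L,
    residential_zip = sample(zips, nx, replace = TRUE),
    race_i = sample(names(cfg$race_distribution), nx, replace = TRUE, prob = cfg$race_distribution),
    case_id = if (srow$has_case_ids) {
      sprintf("%s-HX%04d", state, seq_len(nx))
    } else {
      NA_character_
    },
    sex = sample(c("F", "M"), nx, replace = TRUE),
    fac_i = sample.int(n_fac, nx, replace = TRUE),
    own_claims = stats::runif(nx) >= srow$newborn_billed_under_mother_prob &
      stats::runif(nx) < srow$code_coverage
  )
  extra$enrollment_start <- extra$dob + sample(0:1, nx, replace = TRUE)
  xcl <- extra[extra$own_claims, ]
  xcodes <- sample_codes(cfg$code_lists, "newborn_care", nrow(xcl))
  extra_claims <- tibble::tibble(
    beneficiary_id = xcl$infant_id, state = state,
    service_date = xcl$dob + sample(0:2, nrow(xcl), replace = TRUE),
    code = xcodes$code, code_system = xcodes$system,
    provider_npi = fac$npi[xcl$fac_i], source_file = "other_services"
  )

  mother_enrollment <- tidyr::crossing(
    dplyr::select(
      mothers, beneficiary_id = "mother_id", date_of_birth = "mother_dob",
      "residential_zip", race_ethnicity = "race", "case_id"
    ),
    year = cfg$years
  ) |>
    dplyr::mutate(
      state = state, sex = "F",
      enrollment_start = .data$date_of_birth + 6570 # enrolled since age ~18
    )
  infant_enrollment <- tibble::tibble(
    beneficiary_id = inf$infant_id, state = state,
    year = as.integer(format(inf$dob, "%Y")),
    date_of_birth = inf$dob, enrollment_start = inf$enrollment_start,
    residential_zip = inf$residential_zip, race_ethnicity = inf$race_i,
    case_id = inf$case_id, sex = inf$sex
  )
  extra_enrollment <- tibble::tibble(
    beneficiary_id = extra$infant_id, state = state,
    year = as.integer(format(extra$dob, "%Y")),
    date_of_birth = extra$dob, enrollment_start = extra$enrollment_start,
    residential_zip = extra$residential_zip, race_ethnicity = extra$race_i,
    case_id = extra$case_id, sex = extra$sex
  )

  truth <- dplyr::bind_rows(
    tibble::tibble(
      mother_id = inf$mother_id, infant_id = inf$infant_id, state = state,
      true_delivery_date = inf$delivery_date,
      household_case_id = inf$case_id, twin = inf$twin,
      medicaid_delivery = TRUE
    ),
    tibble::tibble(
      mother_id = NA_character_, infant_id = extra$infant_id, state = state,
      true_delivery_date = extra$dob,
      household_case_id = extra$case_id, twin = FALSE,
      medicaid_delivery = FALSE
    )
  )

  list(
    claims = dplyr::bind_rows(
      delivery_claims, mg_claims, newborn_claims, mg_inf_claims, extra_claims
    ),
    enrollment = dplyr::bind_rows(
      mother_enrollment, infant_enrollment, extra_enrollment
    ),
    npi_table = tidyr::crossing(fac, year = c(cfg$years, max(cfg$years) + 1L)) |>
      dplyr::select("npi", "year", "zip"),
    truth = truth,
    n_deliveries = tibble::tibble(
      state = state,
      year = as.integer(format(deliveries$delivery_date, "%Y"))
    ) |>
      dplyr::count(.data$state, .data$year, name = "true_deliveries")
  )
}

#' Generate a synthetic claims universe with ground-truth dyads
#'
#' Produces claims, enrollment, an NPI-to-ZIP table, benchmark birth counts
#' and a ground-truth dyad table, deterministic given the configuration seed.
#' Matching-variable missingness is applied after assembly: residential ZIP,
#' race/ethnicity and case ID are masked independently per enrollment record,
#' and the facility signal is masked by removing the provider NPI from claim
#' lines. Benchmark counts are the true per-state-year Medicaid delivery
#' counts thinned by the payer-misreport rate.
#'
#' @param config A [synth_config()].
#' @return A list of class `dyadlink_synth` with tibbles `claims`,
#'   `enrollment`, `npi_table`, `nvss`, `truth`, plus the `code_lists` and
#'   `config` used.
#' @export
#' @examples
#' synth <- synth_generate(synth_config(seed = 7))
#' nrow(synth$truth)
synth_generate <- function(config = synth_config()) {
  withr::with_seed(config$seed, synth_generate_impl(config))
}

synth_generate_impl <- function(cfg) {
  parts <- purrr::map(seq_len(nrow(cfg$states)), function(i) {
    gen_state(cfg$states[i, ], i, cfg)
  })
  claims <- purrr::map(parts, "claims") |> purrr::list_rbind()
  enrollment <- purrr::map(parts, "enrollment") |> purrr::list_rbind()
  npi_table <- purrr::map(parts, "npi_table") |> purrr::list_rbind()
  truth <- purrr::map(parts, "truth") |> purrr::list_rbind()
  true_deliveries <- purrr::map(parts, "n_deliveries") |> purrr::list_rbind()

  # per-variable masking at configured rates
  m <- cfg$missingness
  mask <- function(x, rate) {
    x[stats::runif(length(x)) < rate] <- NA
    x
  }
  enrollment$residential_zip <- mask(enrollment$residential_zip, m[["residential_zip"]])
  enrollment$race_ethnicity <- mask(enrollment$race_ethnicity, m[["race_ethnicity"]])
  enrollment$case_id <- mask(enrollment$case_id, m[["case_id"]])
  claims$provider_npi <- mask(claims$provider_npi, m[["facility_zip"]])
  claims$claim_year <- as.integer(format(claims$service_date, "%Y"))

  nvss <- tidyr::crossing(
    state = cfg$states$state, year = cfg$years
  ) |>
    dplyr::left_join(true_deliveries, by = c("state", "year")) |>
    dplyr::mutate(
      true_deliveries = dplyr::coalesce(.data$true_deliveries, 0L),
      medicaid_births = stats::rbinom(
        dplyr::n(), .data$true_deliveries, 1 - cfg$nvss_payer_misreport_rate
      )
    ) |>
    dplyr::select("state", "year", "medicaid_births")

  claims <- claims |>
    dplyr::select(
      "beneficiary_id", "state", "service_date", "code", "code_system",
      "provider_npi", "source_file", "claim_year"
    ) |>
    dplyr::arrange(.data$beneficiary_id, .data$service_date, .data$code)
  enrollment <- dplyr::select(
    enrollment,
    "beneficiary_id", "state", "year", "date_of_birth", "enrollment_start",
    "residential_zip", "race_ethnicity", "case_id", "sex"
  ) |>
    dplyr::arrange(.data$beneficiary_id, .data$year)
  structure(
    list(
      claims = claims, enrollment = enrollment, npi_table = npi_table,
      nvss = nvss, truth = truth, code_lists = cfg$code_lists, config = cfg
    ),
    class = "dyadlink_synth"
  )
}

#' @export
print.dyadlink_synth <- function(x, ...) {
  cat("<dyadlink_synth>\n")
  cat(sprintf(
    "  %d claims, %d enrollment records, %d truth dyad rows, %d states\n",
    nrow(x$claims), nrow(x$enrollment), nrow(x$truth),
    dplyr::n_distinct(x$truth$state)
  ))
  invisible(x)
}

#' Write a synthetic universe to disk
#'
#' Emits the same file formats the readers consume: `claims.csv`,
#' `enrollment.csv`, `npi.csv`, `nvss.csv`, `codes.csv` and
#' `truth_dyads.csv`.
#'
#' @param synth A `dyadlink_synth` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(synth$claims, file.path(dir, "claims.csv"), progress = FALSE)
  readr::write_csv(synth$enrollment, file.path(dir, "enrollment.csv"), progress = FALSE)
  readr::write_csv(synth$npi_table, file.path(dir, "npi.csv"), progress = FALSE)
  readr::write_csv(synth$nvss, file.path(dir, "nvss.csv"), progress = FALSE)
  readr::write_csv(synth$code_lists, file.path(dir, "codes.csv"), progress = FALSE)
  readr::write_csv(synth$truth, file.path(dir, "truth_dyads.csv"), progress = FALSE)
  invisible(dir)
}

#' Score links against ground truth
#'
#' Precision is the share of links whose (mother, infant) pair is a true dyad;
#' recall is the share of eligible true dyads recovered, where an eligible
#' dyad is a singleton birth with a Medicaid-paid delivery. With no links,
#' precision is undefined (`NA`) and recall is zero.
#'
#' @param links A links tibble (`tidy()` of a matching run) or a
#'   `dyad_matching` object.
#' @param truth The `truth` tibble of a [synth_generate()] run.
#' @param by_phase Return per-phase attribution instead of the overall
#'   summary?
#' @return A one-row tibble `n_links`, `n_correct`, `n_eligible_truth`,
#'   `precision`, `recall`; or with `by_phase = TRUE` one row per phase with
#'   `n_links`, `n_correct`, `precision`.
#' @export
score_against_truth <- function(links, truth, by_phase = FALSE) {
  if (inherits(links, "dyad_matching")) links <- links$links
  eligible <- dplyr::filter(truth, !.data$twin, .data$medicaid_delivery)
  scored <- links |>
    dplyr::left_join(
      dplyr::mutate(
        dplyr::distinct(truth, .data$mother_id, .data$infant_id),
        correct = TRUE
      ),
      by = c("mother_id", "infant_id")
    ) |>
    dplyr::mutate(correct = dplyr::coalesce(.data$correct, FALSE))
  if (by_phase) {
    return(
      scored |>
        dplyr::group_by(.data$phase) |>
        dplyr::summarise(
          n_links = dplyr::n(), n_correct = sum(.data$correct),
          precision = mean(.data$correct), .groups = "drop"
        )
    )
  }
  tibble::tibble(
    n_links = nrow(scored),
    n_correct = sum(scored$correct),
    n_eligible_truth = nrow(eligible),
    precision = if (nrow(scored) > 0) mean(scored$correct) else NA_real_,
    recall = sum(scored$correct) / max(1, nrow(eligible))
  )
}
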