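#' Determine each beneficiary's date of birth from enrollment records
#'
#' A birth date is "confidently determined" when all non-missing
#' `date_of_birth` values across a beneficiary's enrollment records agree.
#' Conflicting values, or no recorded value at all, leave the date
#' undetermined (`NA` with the corresponding `dob_status`).
#'
#' @param enrollment Enrollment tibble (see [read_enrollment()]).
#' @return A tibble with one row per beneficiary: `beneficiary_id`, `state`
#'   (from the earliest-year record), `date_of_birth`, and `dob_status`
#'   (`"ok"`, `"conflict"` or `"missing"`).
#' @export
determine_dob <- function(enrollment) {
  assert_columns(enrollment, c("beneficiary_id", "state", "year", "date_of_birth"))
  enrollment |>
    dplyr::arrange(.data$beneficiary_id, .data$year) |>
    dplyr::group_by(.data$beneficiary_id) |>
    dplyr::summarise(
      state = dplyr::first(.data$state),
      n_dob = dplyr::n_distinct(.data$date_of_birth[!is.na(.data$date_of_birth)]),
      date_of_birth = if (.data$n_dob[1] == 1) {
        min(.data$date_of_birth, na.rm = TRUE)
      } else {
        as.Date(NA)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dob_status = dplyr::case_when(
        n_dob == 1 ~ "ok",
        n_dob == 0 ~ "missing",
        TRUE ~ "conflict"
      )
    ) |>
    dplyr::select("beneficiary_id", "state", "date_of_birth", "dob_status")
}

#' Select beneficiaries with newborn-care claims shortly after birth
#'
#' Returns beneficiaries carrying at least one newborn-care-coded claim whose
#' service date falls between the birth date and
#' `newborn_claim_lookahead` days after it (both inclusive).
#'
#' @param claims Claims tibble.
#' @param code_lists Code-list tibble; only the `newborn_care` role is used.
#' @param dob_table Output of [determine_dob()].
#' @param config A [pipeline_config()].
#' @return A tibble `beneficiary_id`, `state`, `date_of_birth` of code-based
#'   newborns (one row each).
#' @export
select_newborn_claims <- function(claims, code_lists, dob_table,
                                  config = pipeline_config()) {
  nb_codes <- dplyr::filter(code_lists, .data$role == "newborn_care")
  nb_claims <- dplyr::semi_join(claims, nb_codes,
    by = c("code" = "code", "code_system" = "system")
  )
  dob_ok <- dob_table |>
    dplyr::filter(.data$dob_status == "ok") |>
    dplyr::mutate(dob_hi = .data$date_of_birth + config$newborn_claim_lookahead)
  dplyr::inner_join(
    dplyr::select(dob_ok, "beneficiary_id", "state", "date_of_birth", "dob_hi"),
    dplyr::select(nb_claims, "beneficiary_id", "service_date"),
    by = dplyr::join_by(
      "beneficiary_id",
      between(y$service_date, x$date_of_birth, x$dob_hi)
    )
  ) |>
    dplyr::distinct(.data$beneficiary_id, .data$state, .data$date_of_birth)
}

#' Compare code-based newborn counts against vital-statistics benchmarks
#'
#' For every state-year, computes the ratio of code-based newborn count to the
#' benchmark count of Medicaid-payer births. The enrollment fallback activates
#' where the ratio is strictly below the threshold (default 0.95); a zero
#' benchmark leaves the ratio undefined and activates the fallback.
#'
#' @param code_counts Tibble `state`, `year`, `code_based_count` (state-years
#'   with no code-based newborns may simply be absent; they count as zero).
#' @param nvss Benchmark tibble (see [read_nvss()]).
#' @param config A [pipeline_config()].
#' @return A tibble `state`, `year`, `code_based_count`, `nvss_count`,
#'   `coverage_ratio`, `fallback_active`, one row per benchmark state-year.
#' @export
compute_coverage <- function(code_counts, nvss, config = pipeline_config()) {
  assert_columns(nvss, c("state", "year", "medicaid_births"), "NVSS table")
  missing_ny <- dplyr::anti_join(code_counts, nvss, by = c("state", "year"))
  if (nrow(missing_ny) > 0) {
    stop(
      "no NVSS benchmark for state-year(s): ",
      paste(paste(missing_ny$state, missing_ny$year), collapse = "; "),
      call. = FALSE
    )
  }
  nvss |>
    dplyr::left_join(code_counts, by = c("state", "year")) |>
    dplyr::mutate(
      code_based_count = dplyr::coalesce(.data$code_based_count, 0L),
      nvss_count = .data$medicaid_births,
      coverage_ratio = dplyr::if_else(
        .data$nvss_count > 0,
        .data$code_based_count / .data$nvss_count,
        NA_real_
      ),
      fallback_active = is.na(.data$coverage_ratio) |
        .data$coverage_ratio < config$coverage_threshold
    ) |>
    dplyr::select(
      "state", "year", "code_based_count", "nvss_count",
      "coverage_ratio", "fallback_active"
    )
}

#' Enrollment-based newborn fallback
#'
#' For state-years where code-based identification under-covers the benchmark,
#' adds as newborn candidates all beneficiaries born in that state-year whose
#' Medicaid enrollment started before, at, or up to `enrollment_dob_slack`
#' days after their date of birth.
#'
#' @param enrollment Enrollment tibble.
#' @param dob_table Output of [determine_dob()].
#' @param coverage Output of [compute_coverage()].
#' @param config A [pipeline_config()].
#' @return A tibble `beneficiary_id`, `state`, `date_of_birth` of
#'   enrollment-based candidates (may overlap code-based ones; the caller
#'   resolves precedence).
#' @export
enrollment_fallback <- function(enrollment, dob_table, coverage,
                                config = pipeline_config()) {
  fb <- dplyr::filter(coverage, .data$fallback_active)
  if (nrow(fb) == 0) {
    return(tibble::tibble(
      beneficiary_id = character(), state = character(),
      date_of_birth = as.Date(character())
    ))
  }
  dob_ok <- dplyr::filter(dob_table, .data$dob_status == "ok")
  enrollment |>
    dplyr::inner_join(
      dplyr::select(dob_ok, "beneficiary_id", dob = "date_of_birth"),
      by = "beneficiary_id"
    ) |>
    dplyr::filter(
      !is.na(.data$enrollment_start),
      .data$enrollment_start <= .data$dob + config$enrollment_dob_slack,
      # age-0 requirement: born in the fallback state-year itself
      as.integer(format(.data$dob, "%Y")) == .data$year
    ) |>
    dplyr::semi_join(fb, by = c("state", "year")) |>
    dplyr::distinct(.data$beneficiary_id, .data$state, date_of_birth = .data$dob)
}

#' Identify newborn Medicaid beneficiaries
#'
#' Runs the full newborn-identification stage: determine birth dates from
#' enrollment, find code-based newborns (newborn-care claims within the
#' post-birth lookahead), compare per-state-year code-based counts against the
#' vital-statistics benchmark, and apply the enrollment fallback where
#' coverage falls below the threshold. Candidates found both ways are labeled
#' `code_based`. Multiple-gestation flags come from any claim in the
#' post-birth window carrying a multiple-gestation code; flagged candidates
#' get `excluded_reason = "multiple_gestation"` but remain in the output (the
#' benchmark comparison is made before the singleton exclusion).
#'
#' @param claims Claims tibble.
#' @param enrollment Enrollment tibble.
#' @param code_lists Code-list tibble.
#' @param nvss Benchmark tibble (see [read_nvss()]).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per candidate: `infant_id`, `state`,
#'   `date_of_birth`, `birth_year`, `source` (`"code_based"` or
#'   `"enrollment_based"`), `multiple_gestation`, `excluded_reason`.
#'   Attributes: `coverage` (the [compute_coverage()] table) and `exclusions`
#'   (flow accounting, including newborn-coded beneficiaries dropped for
#'   undetermined birth dates).
#' @export
identify_newborns <- function(claims, enrollment, code_lists, nvss,
                              config = pipeline_config()) {
  dob_table <- determine_dob(enrollment)
  code_based <- select_newborn_claims(claims, code_lists, dob_table, config)

  # beneficiaries with newborn-care claims but no confident birth date
  nb_codes <- dplyr::filter(code_lists, .data$role == "newborn_care")
  nb_bene <- dplyr::semi_join(claims, nb_codes,
    by = c("code" = "code", "code_system" = "system")
  ) |>
    dplyr::distinct(.data$beneficiary_id, .data$state)
  no_dob <- nb_bene |>
    dplyr::semi_join(
      dplyr::filter(dob_table, .data$dob_status != "ok"),
      by = "beneficiary_id"
    )

  counts <- code_based |>
    dplyr::mutate(year = as.integer(format(.data$date_of_birth, "%Y"))) |>
    dplyr::count(.data$state, .data$year, name = "code_based_count")
  coverage <- compute_coverage(counts, nvss, config)
  fallback <- enrollment_fallback(enrollment, dob_table, coverage, config)

  candidates <- dplyr::bind_rows(
    dplyr::mutate(code_based, source = "code_based"),
    dplyr::mutate(
      dplyr::anti_join(fallback, code_based, by = "beneficiary_id"),
      source = "enrollment_based"
    )
  )

  mg_codes <- dplyr::filter(code_lists, .data$role == "multiple_gestation")
  mg_claims <- dplyr::semi_join(claims, mg_codes,
    by = c("code" = "code", "code_system" = "system")
  )
  mg_hit <- dplyr::inner_join(
    dplyr::mutate(candidates, dob_hi = .data$date_of_birth + config$newborn_claim_lookahead),
    dplyr::select(mg_claims, "beneficiary_id", "service_date"),
    by = dplyr::join_by("beneficiary_id", between(y$service_date, x$date_of_birth, x$dob_hi))
  ) |>
    dplyr::distinct(.data$beneficiary_id)

  out <- candidates |>
    dplyr::mutate(
      birth_year = as.integer(format(.data$date_of_birth, "%Y")),
      multiple_gestation = .data$beneficiary_id %in% mg_hit$beneficiary_id,
      excluded_reason = dplyr::if_else(
        .data$multiple_gestation, "multiple_gestation", "none"
      )
    ) |>
    dplyr::rename(infant_id = "beneficiary_id") |>
    dplyr::bind_rows(
      no_dob |>
        dplyr::rename(infant_id = "beneficiary_id") |>
        dplyr::mutate(
          date_of_birth = as.Date(NA), birth_year = NA_integer_,
          source = "code_based", multiple_gestation = FALSE,
          excluded_reason = "no_confident_dob"
        )
    ) |>
    dplyr::select(
      "infant_id", "state", "date_of_birth", "birth_year", "source",
      "multiple_gestation", "excluded_reason"
    )

  attr(out, "coverage") <- coverage
  attr(out, "exclusions") <- list(
    newborns_code_based = nrow(code_based),
    newborns_enrollment_based = sum(out$source == "enrollment_based"),
    newborns_no_confident_dob = nrow(no_dob),
    newborns_multiple_gestation = sum(out$excluded_reason == "multiple_gestation"),
    newborns_retained = sum(out$excluded_reason == "none")
  )
  out
}
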