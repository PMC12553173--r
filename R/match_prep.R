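#' Clean case IDs for matching
#'
#' A case ID is only informative for household matching when it is genuinely
#' household-level. This sets to missing: syntactically invalid IDs (empty or
#' matching a configured sentinel pattern such as all-zeros) and IDs assigned
#' to more than `max_case_id_household_size` distinct beneficiaries within a
#' state-year. The operation is idempotent.
#'
#' @param enrollment Enrollment tibble.
#' @param config A [pipeline_config()].
#' @return The enrollment tibble with `case_id` cleaned.
#' @export
clean_case_ids <- function(enrollment, config = pipeline_config()) {
  x <- enrollment
  cid <- as.character(x$case_id)
  bad <- !is.na(cid) & (cid == "" | Reduce(
    `|`,
    lapply(config$case_id_sentinels, function(p) stringr::str_detect(cid, p)),
    rep(FALSE, length(cid))
  ))
  cid[bad] <- NA_character_
  x$case_id <- cid

  big <- x |>
    dplyr::filter(!is.na(.data$case_id)) |>
    dplyr::group_by(.data$state, .data$year, .data$case_id) |>
    dplyr::summarise(n_bene = dplyr::n_distinct(.data$beneficiary_id), .groups = "drop") |>
    dplyr::filter(.data$n_bene > config$max_case_id_household_size)
  x |>
    dplyr::left_join(
      dplyr::mutate(big, .oversized = TRUE),
      by = c("state", "year", "case_id")
    ) |>
    dplyr::mutate(
      case_id = dplyr::if_else(dplyr::coalesce(.data$.oversized, FALSE),
        NA_character_, .data$case_id
      )
    ) |>
    dplyr::select(-"n_bene", -".oversized")
}

#' Harmonize race/ethnicity for matching
#'
#' Multiracial identities show low recorded congruence between mothers and
#' infants, so they are removed from the matching key (set to missing) while
#' the original `race_ethnicity` value is retained for reporting in a
#' `race_reported` column. Idempotent.
#'
#' @param enrollment Enrollment tibble.
#' @return The enrollment tibble with `race_ethnicity` cleaned for matching
#'   and the original values in `race_reported`.
#' @export
clean_race <- function(enrollment) {
  x <- enrollment
  if (!"race_reported" %in% names(x)) {
    x$race_reported <- x$race_ethnicity
  }
  x$race_ethnicity <- dplyr::if_else(
    x$race_reported == "Multiracial", NA_character_, x$race_reported
  )
  x
}

#' Clean enrollment records for matching
#'
#' Applies [clean_case_ids()], [clean_race()] and residential-ZIP validation
#' (5 digits, not the all-zero placeholder) in one pass. Idempotent.
#'
#' @inheritParams clean_case_ids
#' @return The cleaned enrollment tibble.
#' @export
clean_enrollment <- function(enrollment, config = pipeline_config()) {
  x <- clean_race(clean_case_ids(enrollment, config))
  x$residential_zip <- ifelse(valid_zip(x$residential_zip),
    x$residential_zip, NA_character_
  )
  x
}

#' Resolve facility ZIP codes from claims via the NPI registry
#'
#' Each claim's provider NPI is looked up in the NPI table for the year the
#' claim was filed. Within a group of claims (one delivery's cluster, or one
#' newborn's post-birth claims) the modal resolved ZIP wins; ties are broken
#' by the earliest claim date carrying a tied ZIP, then lexicographically.
#'
#' @param claims Claims tibble restricted to the relevant rows, with a grouping
#'   column named in `group`.
#' @param npi_table NPI lookup tibble (see [read_npi_table()]).
#' @param group Name of the column identifying the entity (e.g.
#'   `"delivery_id"` or `"infant_id"`).
#' @return A tibble with one row per group value: `<group>`, `facility_zip`
#'   (missing when no claim resolves).
#' @export
resolve_facility_zip <- function(claims, npi_table, group) {
  assert_columns(claims, c(group, "provider_npi", "claim_year", "service_date"))
  resolved <- claims |>
    dplyr::filter(!is.na(.data$provider_npi)) |>
    dplyr::inner_join(npi_table,
      by = c("provider_npi" = "npi", "claim_year" = "year")
    )
  if (nrow(resolved) == 0) {
    out <- tibble::tibble(g = unique(claims[[group]]), facility_zip = NA_character_)
    names(out)[1] <- group
    return(out)
  }
  resolved |>
    dplyr::group_by(.data[[group]], .data$zip) |>
    dplyr::summarise(
      n = dplyr::n(), first_date = min(.data$service_date),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$n), .data$first_date, .data$zip,
      .by_group = TRUE
    ) |>
    dplyr::summarise(facility_zip = .data$zip[1], .groups = "drop") |>
    dplyr::right_join(
      tibble::tibble(!!group := unique(claims[[group]])),
      by = group
    )
}

# Pick, for each (beneficiary, target year), the enrollment record of that
# year, else the nearest available year (earlier preferred on ties).
nearest_year_enrollment <- function(targets, enrollment) {
  dplyr::inner_join(targets, enrollment,
    by = "beneficiary_id", relationship = "many-to-many"
  ) |>
    dplyr::mutate(.dist = abs(.data$year - .data$target_year)) |>
    dplyr::arrange(.data$.dist, .data$year) |>
    dplyr::distinct(.data$.id, .keep_all = TRUE) |>
    dplyr::select(-".dist")
}

#' Attach matching keys to deliveries or newborns
#'
#' Derives the four matching variables for each record: residential ZIP,
#' race/ethnicity and case ID from the cleaned enrollment record of the event
#' year (delivery midpoint year, or birth year), falling back to the nearest
#' available year (earlier preferred on ties); and facility ZIP from the
#' record's claims via the NPI registry (a delivery uses the claims in its
#' cluster window; a newborn uses claims within the post-birth lookahead).
#'
#' @param x A deliveries tibble from [identify_deliveries()] or a newborns
#'   tibble from [identify_newborns()] (recognized by its columns).
#' @param claims Claims tibble (the full claim universe).
#' @param enrollment Enrollment tibble, ideally already passed through
#'   [clean_enrollment()] (applied here if the `race_reported` marker column
#'   is absent).
#' @param npi_table NPI lookup tibble.
#' @param config A [pipeline_config()].
#' @return `x` with added columns `residential_zip`, `facility_zip`,
#'   `race_ethnicity`, `case_id`. Attribute `missingness` tallies missing
#'   values per matching variable.
#' @export
attach_match_keys <- function(x, claims, enrollment, npi_table,
                              config = pipeline_config()) {
  if (!"race_reported" %in% names(enrollment)) {
    enrollment <- clean_enrollment(enrollment, config)
  }
  is_delivery <- "delivery_id" %in% names(x)
  id_col <- if (is_delivery) "delivery_id" else "infant_id"
  bene_col <- if (is_delivery) "mother_id" else "infant_id"

  targets <- tibble::tibble(
    .id = x[[id_col]],
    beneficiary_id = x[[bene_col]],
    target_year = if (is_delivery) {
      as.integer(format(x$midpoint, "%Y"))
    } else {
      x$birth_year
    }
  ) |>
    dplyr::filter(!is.na(.data$target_year))
  keys <- nearest_year_enrollment(targets, enrollment) |>
    dplyr::select(".id", "residential_zip", "race_ethnicity", "case_id")

  if (is_delivery) {
    ent_claims <- dplyr::inner_join(
      dplyr::select(x, .id = "delivery_id",
        bene = "mother_id", ws = "window_start", we = "window_end"
      ),
      dplyr::select(claims, bene = "beneficiary_id", "service_date",
        "provider_npi", "claim_year"
      ),
      by = dplyr::join_by("bene", between(y$service_date, x$ws, x$we))
    )
  } else {
    ent_claims <- dplyr::inner_join(
      dplyr::select(x, .id = "infant_id", dob = "date_of_birth") |>
        dplyr::filter(!is.na(.data$dob)) |>
        dplyr::mutate(dob_hi = .data$dob + config$newborn_claim_lookahead),
      dplyr::select(claims, .id2 = "beneficiary_id", "service_date",
        "provider_npi", "claim_year"
      ),
      by = dplyr::join_by(x$.id == y$.id2, between(y$service_date, x$dob, x$dob_hi))
    )
  }
  fzip <- resolve_facility_zip(ent_claims, npi_table, ".id")

  out <- x |>
    dplyr::left_join(keys, by = setNames(".id", id_col)) |>
    dplyr::left_join(fzip, by = setNames(".id", id_col))
  attr(out, "missingness") <- tibble::tibble(
    variable = c("residential_zip", "facility_zip", "race_ethnicity", "case_id"),
    n_missing = c(
      sum(is.na(out$residential_zip)), sum(is.na(out$facility_zip)),
      sum(is.na(out$race_ethnicity)), sum(is.na(out$case_id))
    ),
    n_total = nrow(out)
  )
  out
}
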