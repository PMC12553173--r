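#' Select delivery-coded claims from age-eligible beneficiaries
#'
#' Keeps claim lines carrying a delivery code whose beneficiary was between
#' `min_age` and `max_age` (inclusive, completed years) at the service date.
#' Beneficiary birth dates come from enrollment via [determine_dob()];
#' beneficiaries without a confidently determined birth date are excluded and
#' counted in the `exclusions` attribute.
#'
#' @param claims Claims tibble (see [read_claims()]).
#' @param code_lists Code-list tibble (see [load_code_list()]); only the
#'   `delivery` role is used.
#' @param enrollment Enrollment tibble (see [read_enrollment()]).
#' @param config A [pipeline_config()].
#' @return Tibble of retained delivery claim lines with an added
#'   `age_at_claim` column. Attribute `exclusions` tallies beneficiaries
#'   removed for missing birth dates and claims removed by the age filter.
#' @export
select_delivery_claims <- function(claims, code_lists, enrollment,
                                   config = pipeline_config()) {
  assert_columns(claims, c("beneficiary_id", "state", "service_date", "code", "code_system"))
  delivery_codes <- dplyr::filter(code_lists, .data$role == "delivery")
  x <- dplyr::semi_join(claims, delivery_codes,
    by = c("code" = "code", "code_system" = "system")
  )
  dob <- determine_dob(enrollment)
  x <- dplyr::left_join(
    x, dplyr::select(dob, "beneficiary_id", dob = "date_of_birth"),
    by = "beneficiary_id"
  )
  no_dob <- dplyr::filter(x, is.na(.data$dob))
  x <- dplyr::filter(x, !is.na(.data$dob)) |>
    dplyr::mutate(age_at_claim = age_in_years(.data$dob, .data$service_date))
  age_out <- dplyr::filter(
    x,
    .data$age_at_claim < config$min_age | .data$age_at_claim > config$max_age
  )
  x <- dplyr::filter(
    x,
    .data$age_at_claim >= config$min_age, .data$age_at_claim <= config$max_age
  ) |>
    dplyr::select(-"dob")
  attr(x, "exclusions") <- list(
    beneficiaries_missing_dob = dplyr::n_distinct(no_dob$beneficiary_id),
    claims_missing_dob = nrow(no_dob),
    claims_age_out_of_range = nrow(age_out)
  )
  x
}

#' Cluster one beneficiary's delivery claim dates into distinct deliveries
#'
#' Agglomerative merging on dates: every claim starts as its own cluster;
#' the pair of clusters with the smallest midpoint distance is merged
#' (recomputing the merged cluster's midpoint) while that distance is below
#' `min_gap`. Ties on distance merge the pair with the earliest left-cluster
#' midpoint, which makes the result independent of input order. Emitted
#' clusters therefore satisfy pairwise midpoint gaps of at least `min_gap`
#' days. A cluster midpoint is the earliest date plus half the span, rounded
#' down to a whole day.
#'
#' @param dates A vector of `Date`s (one beneficiary's delivery claim dates).
#' @param min_gap Minimum inter-delivery midpoint gap in days.
#' @return Integer cluster ids aligned with `dates`, numbered 1..k in
#'   chronological order of cluster midpoint.
#' @export
#' @examples
#' d <- as.Date("2015-01-01") + c(0, 2, 300)
#' cluster_claim_dates(d) # claims 0 and 2 merge; day 300 stands alone
cluster_claim_dates <- function(dates, min_gap = 270) {
  n <- length(dates)
  if (n == 0) {
    return(integer(0))
  }
  ord <- order(dates)
  day <- as.numeric(dates)[ord]
  # clusters are contiguous runs over the sorted dates
  lo <- seq_len(n)
  hi <- seq_len(n)
  mid <- floor((day[lo] + day[hi]) / 2)
  while (length(mid) > 1) {
    gaps <- diff(mid)
    i <- which.min(gaps) # first minimum = earliest left midpoint
    if (gaps[i] >= min_gap) break
    lo <- c(lo[seq_len(i)], if (i + 2 <= length(lo)) lo[(i + 2):length(lo)])
    hi <- c(
      if (i > 1) hi[seq_len(i - 1)], hi[i + 1],
      if (i + 2 <= length(hi)) hi[(i + 2):length(hi)]
    )
    mid <- floor((day[lo] + day[hi]) / 2)
  }
  ids <- integer(n)
  for (k in seq_along(lo)) ids[ord[lo[k]:hi[k]]] <- k
  ids
}

#' Identify unique deliveries resulting in live births
#'
#' Runs the full delivery-identification stage: select delivery-coded claims
#' from age-eligible beneficiaries, cluster each beneficiary's claim dates
#' into distinct deliveries, estimate each delivery's date window, and flag
#' multiple-gestation deliveries. Deliveries whose claim dates span more than
#' `max_window_span` days get `excluded_reason = "wide_window"`; deliveries
#' whose window contains a claim carrying a multiple-gestation code get
#' `excluded_reason = "multiple_gestation"`. Both remain in the output (the
#' benchmark comparison uses all deliveries) but only `excluded_reason ==
#' "none"` rows enter matching.
#'
#' @inheritParams select_delivery_claims
#' @return A tibble with one row per delivery: `delivery_id`, `mother_id`,
#'   `state`, `n_claims`, `claim_dates` (list column), `window_start`,
#'   `window_end`, `midpoint`, `span_days`, `multiple_gestation`,
#'   `excluded_reason`. Attribute `exclusions` extends the claim-selection
#'   tallies with delivery-level exclusion counts.
#' @export
identify_deliveries <- function(claims, enrollment, code_lists,
                                config = pipeline_config()) {
  dc <- select_delivery_claims(claims, code_lists, enrollment, config)
  if (nrow(dc) == 0) {
    out <- tibble::tibble(
      delivery_id = character(), mother_id = character(), state = character(),
      n_claims = integer(), claim_dates = list(),
      window_start = as.Date(character()), window_end = as.Date(character()),
      midpoint = as.Date(character()), span_days = numeric(),
      multiple_gestation = logical(), excluded_reason = character()
    )
    attr(out, "exclusions") <- attr(dc, "exclusions")
    return(out)
  }

  events <- dc |>
    dplyr::distinct(.data$beneficiary_id, .data$state, .data$service_date) |>
    dplyr::arrange(.data$beneficiary_id, .data$state, .data$service_date) |>
    dplyr::group_by(.data$beneficiary_id, .data$state) |>
    dplyr::mutate(
      cluster = cluster_claim_dates(.data$service_date, config$min_interdelivery_gap)
    ) |>
    dplyr::group_by(.data$beneficiary_id, .data$state, .data$cluster) |>
    dplyr::summarise(
      n_claims = dplyr::n(),
      claim_dates = list(.data$service_date),
      window_start = min(.data$service_date),
      window_end = max(.data$service_date),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      midpoint = date_midpoint(.data$window_start, .data$window_end),
      span_days = as.numeric(.data$window_end - .data$window_start) +
        as.numeric(config$window_span_counts_days),
      delivery_id = sprintf("%s-D%02d", .data$beneficiary_id, .data$cluster)
    ) |>
    dplyr::rename(mother_id = "beneficiary_id")

  mg_codes <- dplyr::filter(code_lists, .data$role == "multiple_gestation")
  mg_claims <- dplyr::semi_join(claims, mg_codes,
    by = c("code" = "code", "code_system" = "system")
  )
  mg_hits <- dplyr::inner_join(
    dplyr::select(events, "delivery_id",
      mother_id2 = "mother_id", ws = "window_start", we = "window_end"
    ),
    dplyr::select(mg_claims, mother_id2 = "beneficiary_id", "service_date"),
    by = dplyr::join_by("mother_id2", between(y$service_date, x$ws, x$we))
  ) |>
    dplyr::distinct(.data$delivery_id)

  events <- events |>
    dplyr::mutate(
      multiple_gestation = .data$delivery_id %in% mg_hits$delivery_id,
      excluded_reason = dplyr::case_when(
        .data$span_days > config$max_window_span ~ "wide_window",
        .data$multiple_gestation ~ "multiple_gestation",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(
      "delivery_id", "mother_id", "state", "n_claims", "claim_dates",
      "window_start", "window_end", "midpoint", "span_days",
      "multiple_gestation", "excluded_reason"
    )

  excl <- attr(dc, "exclusions")
  excl$deliveries_total <- nrow(events)
  excl$deliveries_wide_window <- sum(events$excluded_reason == "wide_window")
  excl$deliveries_multiple_gestation <-
    sum(events$excluded_reason == "multiple_gestation")
  excl$deliveries_retained <- sum(events$excluded_reason == "none")
  attr(events, "exclusions") <- excl
  events
}
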