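#' Census region lookup
#'
#' Maps the 50 states plus DC to the four Census regions used in the
#' representativeness table.
#'
#' @return A tibble with columns `state`, `region`.
#' @export
census_regions <- function() {
  tibble::tibble(
    state = c(
      "CT", "ME", "MA", "NH", "RI", "VT", "NJ", "NY", "PA",
      "IL", "IN", "MI", "OH", "WI", "IA", "KS", "MN", "MO", "NE", "ND", "SD",
      "DE", "DC", "FL", "GA", "MD", "NC", "SC", "VA", "WV", "AL", "KY", "MS",
      "TN", "AR", "LA", "OK", "TX",
      "AZ", "CO", "ID", "MT", "NV", "NM", "UT", "WY", "AK", "CA", "HI", "OR", "WA"
    ),
    region = c(
      rep("Northeast", 9), rep("Midwest", 12), rep("South", 17), rep("West", 13)
    )
  )
}

#' Compare identified counts against vital-statistics benchmarks
#'
#' Tabulates identified deliveries and newborns per state-year — before the
#' singleton exclusion, since multiple gestations cannot be separated in the
#' benchmark — against the benchmark count of Medicaid-payer births.
#'
#' @param deliveries Deliveries tibble from [identify_deliveries()].
#' @param newborns Newborns tibble from [identify_newborns()].
#' @param nvss Benchmark tibble (see [read_nvss()]).
#' @return A tibble with one row per state-year: `state`, `year`,
#'   `medicaid_deliveries`, `medicaid_newborns`, `nvss_count`,
#'   `delivery_ratio`, `newborn_ratio`.
#' @export
nvss_comparison <- function(deliveries, newborns, nvss) {
  d_counts <- deliveries |>
    dplyr::mutate(year = as.integer(format(.data$midpoint, "%Y"))) |>
    dplyr::count(.data$state, .data$year, name = "medicaid_deliveries")
  n_counts <- newborns |>
    dplyr::filter(!is.na(.data$birth_year)) |>
    dplyr::count(.data$state, year = .data$birth_year, name = "medicaid_newborns")
  nvss |>
    dplyr::rename(nvss_count = "medicaid_births") |>
    dplyr::left_join(d_counts, by = c("state", "year")) |>
    dplyr::left_join(n_counts, by = c("state", "year")) |>
    dplyr::mutate(
      dplyr::across(
        c("medicaid_deliveries", "medicaid_newborns"),
        ~ dplyr::coalesce(.x, 0L)
      ),
      delivery_ratio = dplyr::if_else(
        .data$nvss_count > 0, .data$medicaid_deliveries / .data$nvss_count, NA_real_
      ),
      newborn_ratio = dplyr::if_else(
        .data$nvss_count > 0, .data$medicaid_newborns / .data$nvss_count, NA_real_
      )
    ) |>
    dplyr::select(
      "state", "year", "medicaid_deliveries", "medicaid_newborns",
      "nvss_count", "delivery_ratio", "newborn_ratio"
    )
}

#' Aggregate over-coverage relative to the benchmark
#'
#' National over-coverage percentages: `100 * (total identified - total
#' benchmark) / total benchmark`, for deliveries and newborns.
#'
#' @param validation Output of [nvss_comparison()].
#' @return A one-row tibble: `delivery_overcoverage_pct`,
#'   `newborn_overcoverage_pct`.
#' @export
overcoverage <- function(validation) {
  tot <- dplyr::summarise(
    validation,
    d = sum(.data$medicaid_deliveries), n = sum(.data$medicaid_newborns),
    v = sum(.data$nvss_count)
  )
  tibble::tibble(
    delivery_overcoverage_pct = 100 * (tot$d - tot$v) / tot$v,
    newborn_overcoverage_pct = 100 * (tot$n - tot$v) / tot$v
  )
}

#' Cumulative match-rate curve
#'
#' The cumulative percentage of deliveries and of newborns linked after each
#' (phase, step) cell of the schedule, nationwide and optionally per state.
#' Curves are monotone non-decreasing; the final values equal the overall
#' match rates.
#'
#' @param result A `dyad_matching` object from [run_matching()].
#' @param by_state Also produce one curve per state?
#' @return A tibble with columns `state` (`"(all)"` for the nationwide curve),
#'   `phase`, `step`, `cell` (1-48 running index), `cum_links`,
#'   `pct_deliveries_linked`, `pct_newborns_linked`.
#' @export
cumulative_match_curve <- function(result, by_state = FALSE) {
  stopifnot(inherits(result, "dyad_matching"))
  cells <- result$schedule |>
    dplyr::select("phase", "step") |>
    dplyr::mutate(cell = dplyr::row_number())
  curve_for <- function(links, n_d, n_n, state_label) {
    per_cell <- dplyr::count(links, .data$phase, .data$step, name = "n_links")
    cells |>
      dplyr::left_join(per_cell, by = c("phase", "step")) |>
      dplyr::mutate(
        n_links = dplyr::coalesce(.data$n_links, 0L),
        cum_links = cumsum(.data$n_links),
        pct_deliveries_linked = 100 * .data$cum_links / max(1, n_d),
        pct_newborns_linked = 100 * .data$cum_links / max(1, n_n),
        state = state_label
      ) |>
      dplyr::select(
        "state", "phase", "step", "cell", "cum_links",
        "pct_deliveries_linked", "pct_newborns_linked"
      )
  }
  out <- curve_for(
    result$links, result$pools$n_deliveries, result$pools$n_newborns, "(all)"
  )
  if (by_state) {
    states <- result$pools$by_state
    per_state <- purrr::pmap(
      list(states$state, states$n_deliveries, states$n_newborns),
      function(s, nd, nn) {
        curve_for(dplyr::filter(result$links, .data$state == s), nd, nn, s)
      }
    )
    out <- dplyr::bind_rows(out, per_state)
  }
  out
}

#' Plot the cumulative match curve
#'
#' @param object A `dyad_matching` object.
#' @param by_state Facet by state?
#' @param ... Unused.
#' @return A ggplot: cumulative percent linked per schedule cell, solid line
#'   for deliveries, dotted for newborns, with phase boundaries marked.
#' @export
autoplot.dyad_matching <- function(object, by_state = FALSE, ...) {
  curve <- cumulative_match_curve(object, by_state = by_state) |>
    tidyr::pivot_longer(
      c("pct_deliveries_linked", "pct_newborns_linked"),
      names_to = "series", values_to = "pct"
    ) |>
    dplyr::mutate(series = dplyr::if_else(
      .data$series == "pct_deliveries_linked", "deliveries", "newborns"
    ))
  n_steps <- dplyr::n_distinct(object$schedule$step)
  p <- ggplot2::ggplot(
    curve,
    ggplot2::aes(x = .data$cell, y = .data$pct, linetype = .data$series)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(
      xintercept = seq(n_steps + 0.5, max(curve$cell), by = n_steps),
      linewidth = 0.2, colour = "grey70"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(deliveries = "solid", newborns = "dotted")
    ) +
    ggplot2::labs(
      x = "matching step (phase boundaries in grey)",
      y = "cumulative % linked", linetype = NULL
    ) +
    ggplot2::theme_minimal()
  if (by_state) p <- p + ggplot2::facet_wrap(~state)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot identified counts against the benchmark
#'
#' @param validation Output of [nvss_comparison()].
#' @return A ggplot comparing identified deliveries and newborns with the
#'   benchmark count per state (summed over years).
#' @export
plot_nvss_comparison <- function(validation) {
  x <- validation |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      Deliveries = sum(.data$medicaid_deliveries),
      Newborns = sum(.data$medicaid_newborns),
      Benchmark = sum(.data$nvss_count),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"state", names_to = "series", values_to = "count")
  ggplot2::ggplot(
    x, ggplot2::aes(x = stats::reorder(.data$state, .data$count),
      y = .data$count, fill = .data$series
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "births", fill = NULL) +
    ggplot2::theme_minimal()
}

demographic_frame <- function(pool, enrollment, role, config) {
  bene_col <- if (role == "delivery") "mother_id" else "infant_id"
  targets <- tibble::tibble(
    .id = pool[[if (role == "delivery") "delivery_id" else "infant_id"]],
    beneficiary_id = pool[[bene_col]],
    target_year = if (role == "delivery") {
      as.integer(format(pool$midpoint, "%Y"))
    } else {
      pool$birth_year
    }
  ) |>
    dplyr::filter(!is.na(.data$target_year))
  demo <- nearest_year_enrollment(targets, enrollment) |>
    dplyr::select(".id",
      race = "race_reported", "sex",
      dplyr::any_of(c("managed_care", "date_of_birth"))
    )
  x <- tibble::tibble(
    .id = pool[[if (role == "delivery") "delivery_id" else "infant_id"]],
    state = pool$state
  ) |>
    dplyr::left_join(demo, by = ".id") |>
    dplyr::left_join(census_regions(), by = "state")
  if (role == "delivery" && "date_of_birth" %in% names(x)) {
    age <- age_in_years(x$date_of_birth, pool$midpoint[match(x$.id, pool$delivery_id)])
    x$age_band <- cut(age,
      breaks = c(-Inf, 19, 24, 29, 34, Inf),
      labels = c("<20", "20-24", "25-29", "30-34", "35+")
    )
  }
  x
}

#' Matched-versus-unmatched representativeness table
#'
#' For each demographic block (region, age band, sex, race/ethnicity and, when
#' an enrollment `managed_care` column is present, managed-care status) the
#' percentage distribution over categories is computed in four populations:
#' all identified records, the pre-match (eligible) pool, matched records, and
#' unmatched records. Age and managed care are tabulated for deliveries only.
#' Percentages are reported to one decimal.
#'
#' @param pool Deliveries or newborns tibble (with `excluded_reason`).
#' @param links Links tibble (`tidy()` of a `dyad_matching`).
#' @param enrollment Enrollment tibble (cleaned or raw; raw race categories
#'   including `Multiracial` are reported).
#' @param role `"delivery"` or `"newborn"`.
#' @param config A [pipeline_config()].
#' @return A tibble: `block`, `category`, `pct_identified`, `pct_prematch`,
#'   `pct_matched`, `pct_unmatched`, plus matching count columns `n_*`.
#' @export
demographics_table <- function(pool, links, enrollment,
                               role = c("delivery", "newborn"),
                               config = pipeline_config()) {
  role <- match.arg(role)
  if (!"race_reported" %in% names(enrollment)) {
    enrollment <- clean_enrollment(enrollment, config)
  }
  id_col <- if (role == "delivery") "delivery_id" else "infant_id"
  frame <- demographic_frame(pool, enrollment, role, config)
  eligible_ids <- pool[[id_col]][pool$excluded_reason == "none"]
  matched_ids <- links[[id_col]]

  blocks <- c("region", "sex", "race")
  if (role == "delivery") {
    if ("age_band" %in% names(frame)) blocks <- c(blocks, "age_band")
    if ("managed_care" %in% names(frame)) blocks <- c(blocks, "managed_care")
  }

  tabulate_pop <- function(ids, suffix) {
    f <- dplyr::filter(frame, .data$.id %in% ids)
    purrr::map(blocks, function(b) {
      v <- f[[b]]
      tab <- table(v, useNA = "no")
      tibble::tibble(
        block = b,
        category = if (length(tab)) names(tab) else character(0),
        n = as.integer(tab),
        pct = round(100 * as.integer(tab) / max(1, sum(!is.na(v))), 1)
      )
    }) |>
      purrr::list_rbind() |>
      dplyr::rename_with(~ paste0(.x, "_", suffix), c("n", "pct"))
  }

  tabulate_pop(frame$.id, "identified") |>
    dplyr::full_join(tabulate_pop(eligible_ids, "prematch"), by = c("block", "category")) |>
    dplyr::full_join(tabulate_pop(matched_ids, "matched"), by = c("block", "category")) |>
    dplyr::full_join(
      tabulate_pop(setdiff(eligible_ids, matched_ids), "unmatched"),
      by = c("block", "category")
    ) |>
    dplyr::mutate(dplyr::across(
      dplyr::starts_with("n_"), ~ dplyr::coalesce(.x, 0L)
    )) |>
    dplyr::select(
      "block", "category",
      "pct_identified", "pct_prematch", "pct_matched", "pct_unmatched",
      dplyr::starts_with("n_")
    )
}
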