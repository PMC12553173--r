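#' Default eight-step relaxation schedule
#'
#' Within every phase the three demographic variables — residential ZIP,
#' facility ZIP, race/ethnicity — are required in progressively smaller
#' subsets: all three, each pair, each single variable, then none. The order
#' among equal-size subsets follows the variable enumeration order and can be
#' overridden by supplying a custom list to [phase_schedule()].
#'
#' @return A list of 8 character vectors of required variable names.
#' @export
default_step_schedule <- function() {
  r <- "residential_zip"
  f <- "facility_zip"
  e <- "race_ethnicity"
  list(c(r, f, e), c(r, f), c(r, e), c(f, e), r, f, e, character(0))
}

#' Build the matching phase schedule
#'
#' The matcher proceeds through six phases of progressively less restrictive
#' criteria. Phases 1-3 require mother and newborn to share a case ID, with
#' the newborn's birth date inside the delivery window widened by 0, 1 and 2
#' days respectively; phases 4-6 drop the case-ID requirement (missing or
#' conflicting case IDs both allowed) with the same window tolerances. Every
#' phase iterates through the eight-step relaxation over the remaining three
#' variables, giving 48 (phase, step) cells.
#'
#' @param date_tolerances Integer vector of window tolerances (days); each
#'   tolerance yields one case-ID-required phase and one case-ID-free phase.
#' @param step_schedule List of required-variable subsets, see
#'   [default_step_schedule()].
#' @return A tibble with columns `phase`, `step`, `date_tolerance`,
#'   `case_id_required`, `vars` (list column).
#' @export
phase_schedule <- function(date_tolerances = c(0, 1, 2),
                           step_schedule = default_step_schedule()) {
  if (length(step_schedule) == 0) stop("step_schedule must be non-empty", call. = FALSE)
  allowed <- c("residential_zip", "facility_zip", "race_ethnicity")
  bad <- setdiff(unlist(step_schedule), allowed)
  if (length(bad) > 0) {
    stop("unknown step variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  phases <- tibble::tibble(
    phase = seq_len(2 * length(date_tolerances)),
    date_tolerance = rep(date_tolerances, times = 2),
    case_id_required = rep(c(TRUE, FALSE), each = length(date_tolerances))
  )
  tidyr::crossing(phases, step = seq_along(step_schedule)) |>
    dplyr::mutate(vars = step_schedule[.data$step]) |>
    dplyr::arrange(.data$phase, .data$step)
}

match_pool_cols <- c("residential_zip", "facility_zip", "race_ethnicity", "case_id")

#' Candidate delivery-newborn pairs for one matching cell
#'
#' A pair is a candidate iff the two records are in the same state; the
#' newborn's date of birth lies within the delivery window widened by
#' `date_tolerance` days on both ends; when `case_id_required`, both case IDs
#' are present and equal; and every variable in `vars` is present on both
#' sides and equal (missing values never match).
#'
#' @param deliveries Delivery pool with matching keys (see
#'   [attach_match_keys()]).
#' @param newborns Newborn pool with matching keys.
#' @param date_tolerance Days by which the delivery window is widened.
#' @param case_id_required Must both records share a present case ID?
#' @param vars Character vector of additionally required variables, a subset
#'   of `residential_zip`, `facility_zip`, `race_ethnicity`.
#' @return A tibble of candidate pairs: `delivery_id`, `mother_id`,
#'   `infant_id`, `state`.
#' @export
candidate_pairs <- function(deliveries, newborns, date_tolerance = 0,
                            case_id_required = FALSE, vars = character(0)) {
  keys <- c("state", if (case_id_required) "case_id", vars)
  d <- deliveries |>
    dplyr::filter(dplyr::if_all(dplyr::all_of(setdiff(keys, "state")), ~ !is.na(.x))) |>
    dplyr::mutate(
      .ws = .data$window_start - date_tolerance,
      .we = .data$window_end + date_tolerance
    )
  n <- newborns |>
    dplyr::filter(
      dplyr::if_all(dplyr::all_of(setdiff(keys, "state")), ~ !is.na(.x)),
      !is.na(.data$date_of_birth)
    )
  by <- rlang::inject(dplyr::join_by(
    !!!rlang::syms(keys),
    between(y$date_of_birth, x$.ws, x$.we)
  ))
  dplyr::inner_join(
    dplyr::select(d, "delivery_id", "mother_id", dplyr::all_of(keys), ".ws", ".we"),
    dplyr::select(n, "infant_id", dplyr::all_of(c(keys, "date_of_birth"))),
    by = by
  ) |>
    dplyr::select("delivery_id", "mother_id", "infant_id", "state")
}

#' Accept mutually unique candidate pairs
#'
#' A candidate pair is accepted only when the delivery participates in exactly
#' one candidate pair and the newborn participates in exactly one candidate
#' pair (mutual degree one). All acceptances within a step are simultaneous:
#' degrees are computed on the full pair set before any acceptance.
#'
#' @param pairs Candidate pair tibble from [candidate_pairs()].
#' @return The subset of `pairs` that are mutually unique.
#' @export
accept_unique <- function(pairs) {
  pairs |>
    dplyr::add_count(.data$delivery_id, name = ".deg_d") |>
    dplyr::add_count(.data$infant_id, name = ".deg_n") |>
    dplyr::filter(.data$.deg_d == 1, .data$.deg_n == 1) |>
    dplyr::select(-".deg_d", -".deg_n")
}

prepare_pool <- function(x, what) {
  required <- switch(what,
    delivery = c("delivery_id", "mother_id", "state", "window_start", "window_end"),
    newborn = c("infant_id", "state", "date_of_birth")
  )
  assert_columns(x, c(required, match_pool_cols), paste(what, "pool"))
  if ("excluded_reason" %in% names(x)) {
    x <- dplyr::filter(x, .data$excluded_reason == "none")
  }
  if (what == "newborn") x <- dplyr::filter(x, !is.na(.data$date_of_birth))
  x
}

#' Run the greedy deterministic matching algorithm
#'
#' Iterates through the schedule's (phase, step) cells in order. In each cell,
#' candidate pairs are formed from the current unmatched pools
#' ([candidate_pairs()]) and mutually unique pairs are accepted
#' ([accept_unique()]); linked deliveries and newborns are removed from the
#' pools before the next cell. Records with `excluded_reason != "none"` never
#' enter the pools. The procedure is deterministic and invariant to input row
#' order.
#'
#' @param deliveries Delivery pool with matching keys.
#' @param newborns Newborn pool with matching keys.
#' @param config A [pipeline_config()]; supplies the default schedule and the
#'   within-step iteration mode.
#' @param schedule A [phase_schedule()] tibble; defaults to the one in
#'   `config`.
#' @return An object of class `dyad_matching` with components `links` (one row
#'   per accepted dyad: `delivery_id`, `mother_id`, `infant_id`, `state`,
#'   `phase`, `step`, `matched_on`), `tallies` (per-cell candidate and link
#'   counts with cumulative totals), `pools` (pool sizes overall and by
#'   state), and `schedule`. Use [tidy()] for the links, [glance()] for
#'   summary rates, and [autoplot()] for the cumulative match curve.
#' @export
run_matching <- function(deliveries, newborns, config = pipeline_config(),
                         schedule = config$phase_schedule) {
  d_pool <- prepare_pool(deliveries, "delivery")
  n_pool <- prepare_pool(newborns, "newborn")
  pools <- list(
    n_deliveries = nrow(d_pool),
    n_newborns = nrow(n_pool),
    by_state = dplyr::full_join(
      dplyr::count(d_pool, .data$state, name = "n_deliveries"),
      dplyr::count(n_pool, .data$state, name = "n_newborns"),
      by = "state"
    ) |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ dplyr::coalesce(.x, 0L)))
  )

  links <- vector("list", nrow(schedule))
  tallies <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    cell <- schedule[i, ]
    vars <- cell$vars[[1]]
    n_pairs_total <- 0L
    cell_links <- list()
    repeat {
      pairs <- candidate_pairs(
        d_pool, n_pool,
        date_tolerance = cell$date_tolerance,
        case_id_required = cell$case_id_required,
        vars = vars
      )
      n_pairs_total <- n_pairs_total + nrow(pairs)
      acc <- accept_unique(pairs)
      if (nrow(acc) > 0) {
        d_pool <- dplyr::filter(d_pool, !.data$delivery_id %in% acc$delivery_id)
        n_pool <- dplyr::filter(n_pool, !.data$infant_id %in% acc$infant_id)
        cell_links <- c(cell_links, list(acc))
      }
      if (!isTRUE(config$iterate_within_step) || nrow(acc) == 0) break
    }
    cell_links <- dplyr::bind_rows(cell_links)
    if (nrow(cell_links) > 0) {
      cell_links <- dplyr::mutate(cell_links,
        phase = cell$phase, step = cell$step,
        matched_on = paste(vars, collapse = "+")
      )
    }
    links[[i]] <- cell_links
    tallies[[i]] <- tibble::tibble(
      phase = cell$phase, step = cell$step,
      date_tolerance = cell$date_tolerance,
      case_id_required = cell$case_id_required,
      required_vars = paste(vars, collapse = "+"),
      n_candidate_pairs = n_pairs_total,
      n_links = nrow(cell_links)
    )
  }
  links <- dplyr::bind_rows(links)
  if (nrow(links) == 0) {
    links <- tibble::tibble(
      delivery_id = character(), mother_id = character(),
      infant_id = character(), state = character(),
      phase = integer(), step = integer(), matched_on = character()
    )
  }
  tallies <- dplyr::bind_rows(tallies) |>
    dplyr::mutate(cum_links = cumsum(.data$n_links))

  stopifnot(
    anyDuplicated(links$delivery_id) == 0,
    anyDuplicated(links$infant_id) == 0
  )
  structure(
    list(links = links, tallies = tallies, pools = pools, schedule = schedule),
    class = "dyad_matching"
  )
}

#' Exhaustive reference implementation of the matcher
#'
#' Evaluates every delivery-newborn pair directly (no blocking or joins) with
#' the same acceptance semantics as [run_matching()]. Intended as an
#' independent cross-check on small pools; quadratic in pool size.
#'
#' @inheritParams run_matching
#' @return A tibble of links with the same columns as
#'   `run_matching(...)$links`.
#' @export
brute_force_match <- function(deliveries, newborns, config = pipeline_config(),
                              schedule = config$phase_schedule) {
  d <- as.data.frame(prepare_pool(deliveries, "delivery"))
  n <- as.data.frame(prepare_pool(newborns, "newborn"))
  d_free <- rep(TRUE, nrow(d))
  n_free <- rep(TRUE, nrow(n))
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    cell <- schedule[i, ]
    vars <- cell$vars[[1]]
    repeat {
      di <- which(d_free)
      ni <- which(n_free)
      if (length(di) == 0 || length(ni) == 0) break
      grid <- expand.grid(d = di, n = ni)
      ok <- d$state[grid$d] == n$state[grid$n] &
        n$date_of_birth[grid$n] >= d$window_start[grid$d] - cell$date_tolerance &
        n$date_of_birth[grid$n] <= d$window_end[grid$d] + cell$date_tolerance
      if (cell$case_id_required) {
        ok <- ok & !is.na(d$case_id[grid$d]) & !is.na(n$case_id[grid$n]) &
          d$case_id[grid$d] == n$case_id[grid$n]
      }
      for (v in vars) {
        ok <- ok & !is.na(d[[v]][grid$d]) & !is.na(n[[v]][grid$n]) &
          d[[v]][grid$d] == n[[v]][grid$n]
      }
      ok[is.na(ok)] <- FALSE
      grid <- grid[ok, , drop = FALSE]
      deg_d <- table(grid$d)
      deg_n <- table(grid$n)
      keep <- deg_d[as.character(grid$d)] == 1 & deg_n[as.character(grid$n)] == 1
      acc <- grid[keep, , drop = FALSE]
      if (nrow(acc) > 0) {
        d_free[acc$d] <- FALSE
        n_free[acc$n] <- FALSE
        out[[length(out) + 1]] <- tibble::tibble(
          delivery_id = d$delivery_id[acc$d],
          mother_id = d$mother_id[acc$d],
          infant_id = n$infant_id[acc$n],
          state = d$state[acc$d],
          phase = cell$phase, step = cell$step,
          matched_on = paste(vars, collapse = "+")
        )
      }
      if (!isTRUE(config$iterate_within_step) || nrow(acc) == 0) break
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      delivery_id = character(), mother_id = character(),
      infant_id = character(), state = character(),
      phase = integer(), step = integer(), matched_on = character()
    ))
  }
  dplyr::bind_rows(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the links of a matching run
#'
#' @param x A `dyad_matching` object.
#' @param ... Unused.
#' @return The links tibble, one row per accepted dyad.
#' @export
tidy.dyad_matching <- function(x, ...) {
  x$links
}

#' One-row summary of a matching run
#'
#' @param x A `dyad_matching` object.
#' @param ... Unused.
#' @return A tibble with `n_dyads`, pool sizes, the percentage of deliveries
#'   and of newborns linked, and the number of dyads from case-ID-required
#'   phases.
#' @export
glance.dyad_matching <- function(x, ...) {
  case_phases <- x$schedule$phase[x$schedule$case_id_required]
  tibble::tibble(
    n_dyads = nrow(x$links),
    n_deliveries = x$pools$n_deliveries,
    n_newborns = x$pools$n_newborns,
    pct_deliveries_linked = 100 * nrow(x$links) / max(1, x$pools$n_deliveries),
    pct_newborns_linked = 100 * nrow(x$links) / max(1, x$pools$n_newborns),
    n_dyads_case_id_phases = sum(x$links$phase %in% case_phases)
  )
}

#' @export
print.dyad_matching <- function(x, ...) {
  g <- glance(x)
  cat("<dyad_matching>\n")
  cat(sprintf(
    "  %d dyads from %d deliveries x %d newborns\n",
    g$n_dyads, g$n_deliveries, g$n_newborns
  ))
  cat(sprintf(
    "  %.2f%% of deliveries and %.2f%% of newborns linked\n",
    g$pct_deliveries_linked, g$pct_newborns_linked
  ))
  by_phase <- dplyr::count(x$links, .data$phase)
  if (nrow(by_phase) > 0) {
    cat("  links by phase:",
      paste(sprintf("%d: %d", by_phase$phase, by_phase$n), collapse = ", "), "\n"
    )
  }
  invisible(x)
}
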