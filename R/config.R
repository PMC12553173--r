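#' Pipeline configuration
#'
#' Collects every tunable threshold of the linkage pipeline in one object.
#' Defaults reflect the method's published operating point: mothers aged 12-50
#' at the delivery claim, delivery episodes whose midpoints are at least 270
#' days apart, delivery windows of 7 or fewer days, newborn-care claims within
#' 7 days of birth, an enrollment fallback for state-years whose code-based
#' newborn count falls below 95% of the vital-statistics benchmark, enrollment
#' up to one day after birth, and case IDs shared by more than 10 beneficiaries
#' in a state-year treated as non-household identifiers.
#'
#' @param min_age,max_age Inclusive age bounds (completed years at the claim
#'   date) for delivery beneficiaries.
#' @param min_interdelivery_gap Minimum gap in days between midpoints of two
#'   distinct deliveries of one beneficiary.
#' @param max_window_span Maximum delivery window length, measured as
#'   `window_end - window_start` in days.
#' @param window_span_counts_days If `TRUE`, measure the window as an inclusive
#'   day count (`end - start + 1`) instead of the end-minus-start difference.
#' @param newborn_claim_lookahead Days after birth within which a newborn-care
#'   claim identifies a newborn.
#' @param coverage_threshold Code-based-count / NVSS-count ratio below which the
#'   enrollment fallback activates for a state-year.
#' @param enrollment_dob_slack Days after birth by which a fallback newborn's
#'   enrollment may start.
#' @param max_case_id_household_size Case IDs held by more than this many
#'   distinct beneficiaries in a state-year are removed.
#' @param case_id_sentinels Character vector of regular expressions; case IDs
#'   matching any of them (or empty) are treated as invalid.
#' @param phase_schedule Matching schedule, see [phase_schedule()].
#' @param iterate_within_step If `TRUE`, re-evaluate uniqueness within a
#'   matching step after each acceptance pass until a fixed point; the default
#'   is a single simultaneous acceptance pass per step.
#'
#' @return A list of class `dyadlink_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_interdelivery_gap
pipeline_config <- function(min_age = 12,
                            max_age = 50,
                            min_interdelivery_gap = 270,
                            max_window_span = 7,
                            window_span_counts_days = FALSE,
                            newborn_claim_lookahead = 7,
                            coverage_threshold = 0.95,
                            enrollment_dob_slack = 1,
                            max_case_id_household_size = 10,
                            case_id_sentinels = c("^0+$", "^9+$"),
                            phase_schedule = dyadlink::phase_schedule(),
                            iterate_within_step = FALSE) {
  num <- c(
    min_age = min_age, max_age = max_age,
    min_interdelivery_gap = min_interdelivery_gap,
    max_window_span = max_window_span,
    newborn_claim_lookahead = newborn_claim_lookahead,
    coverage_threshold = coverage_threshold,
    enrollment_dob_slack = enrollment_dob_slack,
    max_case_id_household_size = max_case_id_household_size
  )
  if (any(num < 0)) {
    stop("all configuration thresholds must be non-negative", call. = FALSE)
  }
  if (min_age > max_age) stop("min_age must not exceed max_age", call. = FALSE)
  if (nrow(phase_schedule) == 0) stop("phase_schedule must be non-empty", call. = FALSE)
  structure(
    list(
      min_age = min_age,
      max_age = max_age,
      min_interdelivery_gap = min_interdelivery_gap,
      max_window_span = max_window_span,
      window_span_counts_days = window_span_counts_days,
      newborn_claim_lookahead = newborn_claim_lookahead,
      coverage_threshold = coverage_threshold,
      enrollment_dob_slack = enrollment_dob_slack,
      max_case_id_household_size = max_case_id_household_size,
      case_id_sentinels = case_id_sentinels,
      phase_schedule = phase_schedule,
      iterate_within_step = iterate_within_step
    ),
    class = "dyadlink_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the file; missing fields take
#' their defaults. The phase schedule itself is configured in code (or with a
#' custom `step_schedule` list under the `phase_schedule` key).
#'
#' @param path Path to a YAML file.
#' @return A `dyadlink_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), c(known, "phase_schedule"))
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(raw$phase_schedule)) {
    ps <- raw$phase_schedule
    raw$phase_schedule <- phase_schedule(
      date_tolerances = ps$date_tolerances %||% c(0, 1, 2),
      step_schedule = ps$step_schedule %||% default_step_schedule()
    )
  }
  do.call(pipeline_config, raw)
}

#' @export
print.dyadlink_config <- function(x, ...) {
  cat("<dyadlink_config>\n")
  for (nm in setdiff(names(x), "phase_schedule")) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  cat(sprintf(
    "  phase_schedule:              %d phases x %d steps\n",
    dplyr::n_distinct(x$phase_schedule$phase),
    dplyr::n_distinct(x$phase_schedule$step)
  ))
  invisible(x)
}
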