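#' Column-mapping dialects
#'
#' Administrative extracts name the same fields differently across data systems
#' (for example a beneficiary identifier column called `BENE_ID` in one system
#' and `MSIS_ID` in another). A dialect maps the canonical in-memory schema to
#' the columns of a particular source file; readers accept one so that files
#' from either system land in a single canonical schema.
#'
#' @param ... Named overrides, canonical field = source column name.
#' @return A named character vector.
#' @export
#' @examples
#' claims_dialect(beneficiary_id = "BENE_ID", service_date = "SRVC_BGN_DT")
claims_dialect <- function(...) {
  default <- c(
    beneficiary_id = "beneficiary_id",
    state = "state",
    service_date = "service_date",
    code = "code",
    code_system = "code_system",
    provider_npi = "provider_npi",
    source_file = "source_file",
    claim_year = "claim_year"
  )
  apply_dialect_overrides(default, list(...), "claims_dialect")
}

#' @rdname claims_dialect
#' @export
enrollment_dialect <- function(...) {
  default <- c(
    beneficiary_id = "beneficiary_id",
    state = "state",
    year = "year",
    date_of_birth = "date_of_birth",
    enrollment_start = "enrollment_start",
    residential_zip = "residential_zip",
    race_ethnicity = "race_ethnicity",
    case_id = "case_id",
    sex = "sex"
  )
  apply_dialect_overrides(default, list(...), "enrollment_dialect")
}

apply_dialect_overrides <- function(default, overrides, what) {
  if (length(overrides) == 0) {
    return(default)
  }
  bad <- setdiff(names(overrides), names(default))
  if (length(bad) > 0 || is.null(names(overrides)) || any(names(overrides) == "")) {
    stop(sprintf(
      "%s: unknown canonical field(s): %s", what,
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  default[names(overrides)] <- unlist(overrides)
  default
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet requires the 'arrow' package", call. = FALSE)
    }
    return(tibble::as_tibble(arrow::read_parquet(path)))
  }
  readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

rename_by_dialect <- function(raw, dialect, what) {
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s: required column(s) not found in file: %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  out <- raw[, unname(dialect), drop = FALSE]
  names(out) <- names(dialect)
  tibble::as_tibble(out)
}

parse_date_field <- function(x) {
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}

new_rejects <- function() {
  tibble::tibble(
    row = integer(), field = character(),
    reason = character(), dropped = logical()
  )
}

add_rejects <- function(log, rows, field, reason, dropped) {
  if (length(rows) == 0) {
    return(log)
  }
  dplyr::bind_rows(log, tibble::tibble(
    row = as.integer(rows), field = field, reason = reason, dropped = dropped
  ))
}

#' Inspect the reject log of a reader
#'
#' Readers never silently drop or blank a value: every dropped row and every
#' field set to missing is recorded with its input row number and a reason.
#' Rows with `dropped = TRUE` were removed; rows with `dropped = FALSE` were
#' kept with the offending field set to missing. The accounting invariant
#' `parsed rows + dropped rejects = input rows` always holds.
#'
#' @param x A tibble returned by [read_claims()], [read_enrollment()],
#'   [read_npi_table()] or [load_code_list()].
#' @return A tibble with columns `row`, `field`, `reason`, `dropped`.
#' @export
rejects <- function(x) {
  attr(x, "rejects") %||% new_rejects()
}

#' Read a claims file
#'
#' Reads delimited (CSV) or parquet claims into the canonical long schema: one
#' row per coded claim line with columns `beneficiary_id`, `state`,
#' `service_date`, `code`, `code_system`, `provider_npi`, `source_file`,
#' `claim_year`. `provider_npi`, `source_file` and `claim_year` may be absent
#' from the source file (pass `NA` in the dialect); `claim_year` is then
#' derived from the service date.
#'
#' @param path Path to a CSV or parquet file.
#' @param dialect A [claims_dialect()]. Map optional canonical fields to `NA`
#'   if the source file lacks them.
#' @return A tibble of claims; the reject log is available via [rejects()].
#' @export
read_claims <- function(path, dialect = claims_dialect()) {
  optional <- c("provider_npi", "source_file", "claim_year")
  absent <- optional[is.na(dialect[optional])]
  dialect <- dialect[!is.na(dialect)]
  raw <- read_table_file(path)
  x <- rename_by_dialect(raw, dialect, "read_claims")
  log <- new_rejects()

  x$.row <- seq_len(nrow(x))
  x$service_date <- parse_date_field(x$service_date)
  bad_date <- which(is.na(x$service_date))
  log <- add_rejects(log, x$.row[bad_date], "service_date", "unparseable date", TRUE)

  x$code_system <- toupper(as.character(x$code_system))
  bad_sys <- which(!x$code_system %in% code_systems())
  bad_sys <- setdiff(bad_sys, bad_date)
  log <- add_rejects(log, x$.row[bad_sys], "code_system", "unknown code system", TRUE)
  drop_rows <- unique(c(bad_date, bad_sys))
  if (length(drop_rows) > 0) x <- x[-drop_rows, , drop = FALSE]

  x$state <- toupper(as.character(x$state))
  if ("provider_npi" %in% names(x)) {
    npi <- stringr::str_trim(as.character(x$provider_npi))
    ok <- !is.na(npi) & stringr::str_detect(npi, "^[0-9]{10}$")
    bad_npi <- which(!ok & !is.na(npi) & npi != "")
    log <- add_rejects(log, x$.row[bad_npi], "provider_npi", "not a 10-digit NPI", FALSE)
    npi[!ok] <- NA_character_
    x$provider_npi <- npi
  } else {
    x$provider_npi <- NA_character_
  }
  if (!"source_file" %in% names(x)) x$source_file <- "other_services"
  if ("claim_year" %in% names(x) && !"claim_year" %in% absent) {
    x$claim_year <- suppressWarnings(as.integer(x$claim_year))
  } else {
    x$claim_year <- NA_integer_
  }
  x$claim_year <- dplyr::coalesce(
    x$claim_year,
    as.integer(format(x$service_date, "%Y"))
  )
  x$.row <- NULL
  out <- tibble::as_tibble(x)
  attr(out, "rejects") <- log
  out
}

#' Read an enrollment/demographics file
#'
#' One row per beneficiary-state-year with demographics and enrollment dates.
#' Duplicate `(beneficiary_id, state, year)` keys are an error. Invalid ZIPs
#' are kept as missing (and logged); 9-digit ZIPs are truncated to 5. Source
#' race/ethnicity values are harmonized to the eight reporting categories via
#' `race_map`; unmapped values become `Unknown/Other` with a logged warning.
#'
#' @param path Path to a CSV or parquet file.
#' @param dialect An [enrollment_dialect()].
#' @param race_map Named character vector mapping source race/ethnicity values
#'   to the canonical categories (`White`, `Hispanic`, `Black`, `Asian`,
#'   `AIAN`, `Hawaiian/PI`, `Multiracial`, `Unknown/Other`). Canonical values
#'   always pass through.
#' @return A tibble of enrollment records; reject log via [rejects()].
#' @export
read_enrollment <- function(path, dialect = enrollment_dialect(),
                            race_map = character()) {
  raw <- read_table_file(path)
  x <- rename_by_dialect(raw, dialect, "read_enrollment")
  log <- new_rejects()
  x$.row <- seq_len(nrow(x))

  x$state <- toupper(as.character(x$state))
  x$year <- suppressWarnings(as.integer(x$year))
  key <- paste(x$beneficiary_id, x$state, x$year, sep = "|")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    stop(
      "duplicate (beneficiary_id, state, year) enrollment key(s): ",
      paste(unique(key[dup]), collapse = "; "),
      call. = FALSE
    )
  }

  for (f in c("date_of_birth", "enrollment_start")) {
    parsed <- parse_date_field(x[[f]])
    bad <- which(is.na(parsed) & !is.na(x[[f]]) & x[[f]] != "")
    log <- add_rejects(log, x$.row[bad], f, "unparseable date", FALSE)
    x[[f]] <- parsed
  }

  zip <- normalize_zip(x$residential_zip)
  bad_zip <- which(is.na(zip) & !is.na(x$residential_zip) & x$residential_zip != "")
  log <- add_rejects(log, x$.row[bad_zip], "residential_zip", "invalid ZIP", FALSE)
  x$residential_zip <- zip

  race <- as.character(x$race_ethnicity)
  mapped <- ifelse(race %in% names(race_map), unname(race_map[race]), race)
  known <- mapped %in% race_levels() | is.na(mapped) | mapped == ""
  log <- add_rejects(
    log, x$.row[!known], "race_ethnicity",
    "unmapped race/ethnicity value -> Unknown/Other", FALSE
  )
  mapped[!known] <- "Unknown/Other"
  mapped[mapped == ""] <- NA_character_
  x$race_ethnicity <- mapped

  sex <- toupper(as.character(x$sex))
  sex[!sex %in% c("F", "M")] <- "Unknown"
  x$sex <- sex
  x$case_id <- as.character(x$case_id)
  x$case_id[x$case_id == ""] <- NA_character_
  x$.row <- NULL
  out <- tibble::as_tibble(x)
  attr(out, "rejects") <- log
  out
}

#' Read an NPI-to-ZIP lookup table
#'
#' Expects columns `npi`, `year`, `zip` (one row per provider-year, NPPES
#' style). Duplicate `(npi, year)` keys are an error; rows with invalid ZIPs
#' are dropped and logged.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `npi`, `year`, `zip`.
#' @export
read_npi_table <- function(path) {
  x <- read_table_file(path)
  assert_columns(x, c("npi", "year", "zip"), "NPI table")
  x <- tibble::tibble(
    npi = as.character(x$npi),
    year = suppressWarnings(as.integer(x$year)),
    zip = normalize_zip(x$zip),
    .row = seq_len(nrow(x))
  )
  key <- paste(x$npi, x$year, sep = "|")
  if (anyDuplicated(key) > 0) {
    stop("duplicate (npi, year) key(s): ",
      paste(unique(key[duplicated(key)]), collapse = "; "),
      call. = FALSE
    )
  }
  log <- add_rejects(new_rejects(), x$.row[is.na(x$zip)], "zip", "invalid ZIP", TRUE)
  out <- dplyr::filter(x, !is.na(.data$zip)) |> dplyr::select(-".row")
  attr(out, "rejects") <- log
  out
}

#' Read state-year vital-statistics birth counts
#'
#' Expects columns `state`, `year`, `medicaid_births`: the number of births
#' for which Medicaid is listed as payer in vital-statistics records, the
#' external benchmark for the coverage check.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `state`, `year`, `medicaid_births`.
#' @export
read_nvss <- function(path) {
  x <- read_table_file(path)
  assert_columns(x, c("state", "year", "medicaid_births"), "NVSS table")
  out <- tibble::tibble(
    state = toupper(as.character(x$state)),
    year = suppressWarnings(as.integer(x$year)),
    medicaid_births = suppressWarnings(as.integer(x$medicaid_births))
  )
  if (any(is.na(out$medicaid_births) | out$medicaid_births < 0)) {
    stop("medicaid_births must be non-negative integers", call. = FALSE)
  }
  key <- paste(out$state, out$year, sep = "|")
  if (anyDuplicated(key) > 0) {
    stop("duplicate (state, year) key(s) in NVSS table", call. = FALSE)
  }
  out
}

#' Load code lists
#'
#' Code lists drive cohort identification: `delivery` codes identify claims
#' for deliveries resulting in live birth, `newborn_care` codes identify
#' claims for newborn care, and `multiple_gestation` codes flag non-singleton
#' births. Accepts CSV (columns `role`, `code`, `system`) or YAML (one list of
#' `{code, system}` entries per role). Content is user-supplied; the package
#' ships only a small illustrative default, see [default_code_lists()].
#'
#' @param path Path to a CSV or YAML code-list file.
#' @return A tibble with columns `role`, `code`, `system`.
#' @export
load_code_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    x <- purrr::imap(raw, function(entries, role) {
      tibble::tibble(
        role = role,
        code = purrr::map_chr(entries, "code"),
        system = purrr::map_chr(entries, "system")
      )
    }) |> purrr::list_rbind()
  } else {
    x <- readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    assert_columns(x, c("role", "code", "system"), "code list")
    x <- x[, c("role", "code", "system")]
  }
  x$system <- toupper(x$system)
  bad_role <- setdiff(unique(x$role), code_roles())
  if (length(bad_role) > 0) {
    stop("unknown code-list role(s): ", paste(bad_role, collapse = ", "),
      call. = FALSE
    )
  }
  bad_sys <- setdiff(unique(x$system), code_systems())
  if (length(bad_sys) > 0) {
    stop("unknown code system(s): ", paste(bad_sys, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(x$code) | x$code == "")) {
    stop("code list contains empty code entries", call. = FALSE)
  }
  n0 <- nrow(x)
  out <- dplyr::distinct(tibble::as_tibble(x))
  if (nrow(out) < n0) {
    warning(sprintf(
      "%d duplicate (role, code, system) entries deduplicated", n0 - nrow(out)
    ), call. = FALSE)
  }
  out
}

#' Illustrative default code lists
#'
#' A deliberately small placeholder set of delivery, newborn-care and
#' multiple-gestation codes used by the synthetic generator and examples.
#' Real analyses must supply their own validated lists via
#' [load_code_list()]; published methods use on the order of a hundred
#' delivery codes.
#'
#' @return A tibble with columns `role`, `code`, `system`.
#' @export
default_code_lists <- function() {
  tibble::tribble(
    ~role, ~code, ~system,
    "delivery", "650", "ICD9-DX",
    "delivery", "O80", "ICD10-DX",
    "delivery", "72.1", "ICD9-PR",
    "delivery", "10E0XZZ", "ICD10-PR",
    "delivery", "59400", "CPT",
    "delivery", "59510", "CPT",
    "newborn_care", "V30.00", "ICD9-DX",
    "newborn_care", "Z38.00", "ICD10-DX",
    "newborn_care", "99460", "CPT",
    "multiple_gestation", "651.01", "ICD9-DX",
    "multiple_gestation", "O30.003", "ICD10-DX",
    "multiple_gestation", "Z38.30", "ICD10-DX"
  )
}

#' Write a run manifest
#'
#' Serializes named stage counts (flow accounting: rows in, retained, excluded
#' by reason) to JSON so a pipeline run documents its exclusion cascade.
#'
#' @param counts A named list of scalar counts (nesting allowed).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(counts, path) {
  jsonlite::write_json(counts, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a stage output table
#'
#' @param x A data frame.
#' @param path Output path; `.csv` or `.parquet` by extension.
#' @return `path`, invisibly.
#' @export
write_stage <- function(x, path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing parquet requires the 'arrow' package", call. = FALSE)
    }
    arrow::write_parquet(x, path)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}
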