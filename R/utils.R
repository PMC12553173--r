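#' @importFrom rlang .data %||%
#' @importFrom stats setNames
NULL

# Normalize a ZIP to its first five digits; anything that does not start with
# five digits (or is the all-zero placeholder) becomes NA.
normalize_zip <- function(zip) {
  zip <- as.character(zip)
  zip <- stringr::str_trim(zip)
  zip <- stringr::str_remove(zip, "-.*$")
  out <- ifelse(stringr::str_detect(zip, "^[0-9]{5}"), substr(zip, 1, 5), NA_character_)
  out[out == "00000"] <- NA_character_
  out
}

valid_zip <- function(zip) {
  !is.na(zip) & stringr::str_detect(zip, "^[0-9]{5}$") & zip != "00000"
}

# Completed years of age at `on`, birthday-based (not calendar-year difference).
age_in_years <- function(dob, on) {
  dob_lt <- as.POSIXlt(dob)
  on_lt <- as.POSIXlt(on)
  age <- on_lt$year - dob_lt$year
  before_birthday <- (on_lt$mon < dob_lt$mon) |
    (on_lt$mon == dob_lt$mon & on_lt$mday < dob_lt$mday)
  age - as.integer(before_birthday)
}

# Midpoint of a date span: earliest date plus floor(half the gap in days).
date_midpoint <- function(first, last) {
  first + floor(as.numeric(last - first) / 2)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

race_levels <- function() {
  c(
    "White", "Hispanic", "Black", "Asian", "AIAN",
    "Hawaiian/PI", "Multiracial", "Unknown/Other"
  )
}

code_systems <- function() {
  c("ICD9-DX", "ICD9-PR", "ICD10-DX", "ICD10-PR", "CPT")
}

code_roles <- function() {
  c("delivery", "newborn_care", "multiple_gestation")
}
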