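D <- function(x) as.Date(x)

# Minimal claims tibble; dates may be given as day offsets from a base date.
make_claims <- function(beneficiary_id, days, code = "O80",
                        code_system = "ICD10-DX", state = "WI",
                        npi = NA_character_, base = D("2015-01-01")) {
  dates <- if (inherits(days, "Date")) days else base + days
  tibble::tibble(
    beneficiary_id = beneficiary_id, state = state, service_date = dates,
    code = code, code_system = code_system, provider_npi = npi,
    source_file = "inpatient",
    claim_year = as.integer(format(dates, "%Y"))
  )
}

make_enrollment <- function(beneficiary_id, year = 2015L,
                            date_of_birth = D("1990-01-01"),
                            enrollment_start = D("2010-01-01"),
                            residential_zip = "53703",
                            race_ethnicity = "White",
                            case_id = NA_character_,
                            sex = "F", state = "WI") {
  tibble::tibble(
    beneficiary_id = beneficiary_id, state = state, year = as.integer(year),
    date_of_birth = date_of_birth, enrollment_start = enrollment_start,
    residential_zip = residential_zip, race_ethnicity = race_ethnicity,
    case_id = case_id, sex = sex
  )
}

# Matching-pool builders with sensible defaults for all required columns.
make_delivery_pool <- function(delivery_id, window_start, window_end = window_start,
                               mother_id = paste0("M-", delivery_id),
                               state = "WI", residential_zip = "53703",
                               facility_zip = "53792", race_ethnicity = "White",
                               case_id = NA_character_) {
  tibble::tibble(
    delivery_id = delivery_id, mother_id = mother_id, state = state,
    window_start = window_start, window_end = window_end,
    residential_zip = residential_zip, facility_zip = facility_zip,
    race_ethnicity = race_ethnicity, case_id = case_id
  )
}

make_newborn_pool <- function(infant_id, date_of_birth, state = "WI",
                              residential_zip = "53703",
                              facility_zip = "53792",
                              race_ethnicity = "White",
                              case_id = NA_character_) {
  tibble::tibble(
    infant_id = infant_id, state = state, date_of_birth = date_of_birth,
    residential_zip = residential_zip, facility_zip = facility_zip,
    race_ethnicity = race_ethnicity, case_id = case_id
  )
}

# Random matching pools with enough key collisions, missingness and date
# offsets that links arise in every phase of the schedule.
make_random_pools <- function(seed, n_d = 60, n_n = 70) {
  withr::with_seed(seed, {
    base <- D("2015-03-01")
    states <- c("AA", "BB")
    zips <- sprintf("1000%d", 1:4)
    fzips <- sprintf("2000%d", 1:3)
    races <- c("White", "Hispanic", "Black")
    cids <- sprintf("H%02d", 1:18)
    pick <- function(pool, n, p_na) {
      x <- sample(pool, n, replace = TRUE)
      x[runif(n) < p_na] <- NA
      x
    }
    ws <- base + sample(0:45, n_d, replace = TRUE)
    deliveries <- tibble::tibble(
      delivery_id = sprintf("D%03d", seq_len(n_d)),
      mother_id = sprintf("M%03d", seq_len(n_d)),
      state = sample(states, n_d, replace = TRUE),
      window_start = ws,
      window_end = ws + sample(0:2, n_d, replace = TRUE),
      residential_zip = pick(zips, n_d, 0.25),
      facility_zip = pick(fzips, n_d, 0.25),
      race_ethnicity = pick(races, n_d, 0.25),
      case_id = pick(cids, n_d, 0.45)
    )
    newborns <- tibble::tibble(
      infant_id = sprintf("N%03d", seq_len(n_n)),
      state = sample(states, n_n, replace = TRUE),
      date_of_birth = base + sample(-2:47, n_n, replace = TRUE),
      residential_zip = pick(zips, n_n, 0.25),
      facility_zip = pick(fzips, n_n, 0.25),
      race_ethnicity = pick(races, n_n, 0.25),
      case_id = pick(cids, n_n, 0.45)
    )
    list(deliveries = deliveries, newborns = newborns)
  })
}

sort_links <- function(links) {
  dplyr::arrange(links, delivery_id, infant_id, phase, step)
}

# --- clustering oracles -------------------------------------------------

# All partitions of n sorted claims into contiguous blocks.
contiguous_partitions <- function(n) {
  if (n == 1) {
    return(list(list(1L)))
  }
  out <- list()
  for (cutset in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(cutset, 2^(0:(n - 2))) > 0)
    bounds <- c(0L, cuts, n)
    out[[length(out) + 1]] <-
      lapply(seq_len(length(bounds) - 1), function(i) (bounds[i] + 1L):bounds[i + 1L])
  }
  out
}

block_midpoint <- function(days, idx) {
  floor((min(days[idx]) + max(days[idx])) / 2)
}

# Does a contiguous partition satisfy pairwise midpoint gaps >= gap?
partition_valid <- function(days, part, gap = 270) {
  mids <- vapply(part, function(ix) block_midpoint(days, ix), numeric(1))
  length(mids) < 2 || all(diff(sort(mids)) >= gap)
}

# Independent greedy simulation over explicit block sets, scanning all block
# pairs for the closest midpoints (ties: earliest left midpoint).
cluster_oracle <- function(dates, gap = 270) {
  ord <- order(dates)
  days <- as.numeric(dates)[ord]
  blocks <- as.list(seq_along(days))
  repeat {
    if (length(blocks) < 2) break
    mids <- vapply(blocks, function(ix) block_midpoint(days, ix), numeric(1))
    best <- NULL
    for (a in seq_along(blocks)) {
      for (b in seq_along(blocks)) {
        if (a == b) next
        dist <- abs(mids[a] - mids[b])
        left <- min(mids[a], mids[b])
        if (is.null(best) || dist < best$dist ||
          (dist == best$dist && left < best$left)) {
          best <- list(a = min(a, b), b = max(a, b), dist = dist, left = left)
        }
      }
    }
    if (best$dist >= gap) break
    merged <- sort(c(blocks[[best$a]], blocks[[best$b]]))
    blocks <- c(blocks[-c(best$a, best$b)], list(merged))
    blocks <- blocks[order(vapply(blocks, function(ix) min(days[ix]), numeric(1)))]
  }
  ids <- integer(length(days))
  for (k in seq_along(blocks)) ids[ord[blocks[[k]]]] <- k
  ids
}

# Perfect-information synthetic regime: unique household case IDs, zero
# missingness, zero jitter, no twins, no stray newborns, exact benchmark.
perfect_synth_config <- function(n_mothers = 4000L, seed = 11L, ...) {
  synth_config(
    states = tibble::tibble(
      state = c("WI", "SC"),
      n_mothers = c(n_mothers, n_mothers),
      has_case_ids = TRUE,
      newborn_billed_under_mother_prob = 0,
      code_coverage = 1
    ),
    twin_rate = 0,
    missingness = c(
      residential_zip = 0, facility_zip = 0,
      race_ethnicity = 0, case_id = 0
    ),
    claim_date_jitter = 0L,
    infant_race_agreement = 1,
    newborn_without_medicaid_delivery_rate = 0,
    late_enrollment_rate = 0,
    nvss_payer_misreport_rate = 0,
    # Multiracial is blanked from the matching key upstream, so a truly
    # missingness-free regime draws from the seven non-multiracial categories
    race_distribution = default_race_distribution()[
      setdiff(names(default_race_distribution()), "Multiracial")
    ],
    seed = seed,
    ...
  )
}
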