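#' Run the full linkage pipeline
#'
#' Convenience wrapper chaining the stages: identify deliveries, identify
#' newborns, clean enrollment, attach matching keys to both pools, and run the
#' six-phase matcher.
#'
#' @param claims Claims tibble.
#' @param enrollment Enrollment tibble.
#' @param code_lists Code-list tibble.
#' @param nvss Benchmark tibble.
#' @param npi_table NPI lookup tibble.
#' @param config A [pipeline_config()].
#' @return A `dyad_matching` object with two extra components: `deliveries`
#'   and `newborns`, the keyed pools (including excluded records) for
#'   downstream reporting.
#' @export
#' @examples
#' synth <- synth_generate(synth_config(seed = 42))
#' fit <- link_dyads(
#'   synth$claims, synth$enrollment, synth$code_lists,
#'   synth$nvss, synth$npi_table
#' )
#' glance(fit)
link_dyads <- function(claims, enrollment, code_lists, nvss, npi_table,
                       config = pipeline_config()) {
  deliveries <- identify_deliveries(claims, enrollment, code_lists, config)
  newborns <- identify_newborns(claims, enrollment, code_lists, nvss, config)
  cleaned <- clean_enrollment(enrollment, config)
  keyed_d <- attach_match_keys(deliveries, claims, cleaned, npi_table, config)
  keyed_n <- attach_match_keys(newborns, claims, cleaned, npi_table, config)
  attr(keyed_d, "exclusions") <- attr(deliveries, "exclusions")
  attr(keyed_n, "exclusions") <- attr(newborns, "exclusions")
  attr(keyed_n, "coverage") <- attr(newborns, "coverage")
  fit <- run_matching(keyed_d, keyed_n, config)
  fit$deliveries <- keyed_d
  fit$newborns <- keyed_n
  fit
}
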