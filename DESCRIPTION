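Package: dyadlink
Title: Deterministic Mother-Infant Dyad Linkage for Medicaid-Style Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies deliveries resulting in live births and newborn
    beneficiaries in administrative health-claims data modeled on Medicaid
    MAX/TAF files, and links them into mother-infant dyads with a greedy
    deterministic six-phase matching algorithm with unique-pair acceptance.
    Includes episode clustering of delivery claims, an enrollment-based
    newborn fallback calibrated against vital-statistics birth counts,
    matching-variable cleaning, validation reporting, and a seeded synthetic
    claims generator with ground-truth dyads for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
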