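---
title: "Linking deliveries to newborns in Medicaid-style claims: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking deliveries to newborns in Medicaid-style claims: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadlink)
library(dplyr)
```

## The problem

Medicaid claims and enrollment files carry no shared identifier between a
mother and her newborn: names and addresses are absent by design, and linkage
to vital records is often impossible or undesirable for privacy reasons.
Studying intergenerational health outcomes nonetheless requires knowing which
newborn beneficiary resulted from which delivery. `dyadlink` implements a
deterministic pipeline that identifies deliveries resulting in live births,
identifies newborn beneficiaries, and links the two pools using only
information already present in claims and enrollment data: state, dates,
residential ZIP, facility ZIP (via the provider registry), race/ethnicity,
and the household case ID where states assign one.

Everything operates on plain tibbles with a canonical schema (one claim line
per row with a single code; one enrollment record per beneficiary-state-year),
so each stage can be run, inspected and tested in isolation.

## Identifying deliveries

Delivery-coded claim lines are selected from beneficiaries aged 12–50 at the
service date. Age is computed in completed years relative to the birthday,
not as a calendar-year difference; the bounds are inclusive on both ends.
Beneficiaries whose birth date cannot be determined from enrollment records
are excluded and counted in the stage's flow accounting.

One delivery generates several claims on nearby dates, and one beneficiary
may have several deliveries over a study period, so each beneficiary's claim
dates are clustered into distinct delivery episodes. The rule is
agglomerative: every claim date starts as its own cluster, and the pair of
clusters with the smallest *midpoint* distance is merged — recomputing the
merged cluster's midpoint — as long as that distance is below 270 days, nine
months being the shortest plausible spacing of two live births. A cluster's
midpoint is its earliest date plus half its span, rounded **down** to a whole
day; the rounding direction is arbitrary but fixed and documented. When two
merges tie on distance, the pair whose left cluster has the earliest midpoint
is merged first. Because the rule only looks at the sorted set of dates, the
result is independent of input row order, and all emitted episodes satisfy
pairwise midpoint gaps of at least 270 days.

The published description of this step names hierarchical clustering and the
270-day midpoint constraint but not the linkage criterion (single linkage,
complete linkage, or something else). The iterative midpoint-merge above is
our reading of the stated constraint — it is the only rule under which "the
midpoint of each delivery period is at least 270 days apart from the midpoint
of any other" is an invariant of the procedure itself rather than a
post-hoc filter. The test suite pins the behaviour against an independent
greedy simulation plus exhaustive enumeration of candidate partitions for up
to six claims.

Each episode's window is `[min claim date, max claim date]`. Deliveries whose
window spans more than 7 days (`window_end - window_start > 7`) cannot be
dated precisely enough for matching and are marked `wide_window`. We measure
the span as an end-minus-start difference; the inclusive day-count reading
(which would exclude at 8 calendar days touched) is available via
`pipeline_config(window_span_counts_days = TRUE)` but not the default.
Episodes whose window contains any claim carrying a multiple-gestation code
are marked `multiple_gestation`; the method links singletons only, because a
twin delivery admits two equally plausible newborns and the unique-match rule
would either drop or mis-assign them. Both kinds of excluded events stay in
the output table (the benchmark comparison needs them) but never enter
matching. When an event is both wide and multiple-gestation, `wide_window` is
reported, mirroring the order of the exclusion cascade.

## Identifying newborns

A beneficiary's birth date is taken as "confidently determined" when all
non-missing `date_of_birth` values across their enrollment records agree;
conflicting records leave the date undetermined and the beneficiary excluded
(with reason `no_confident_dob`). Code-based newborns are beneficiaries with
at least one newborn-care-coded claim between birth and 7 days after it,
inclusive.

Code-based detection fails structurally in states that bill newborn care
under the mother's coverage. The pipeline therefore compares, per state-year,
the code-based newborn count against an external benchmark: the count of
births with Medicaid as payer from vital-statistics records, supplied as an
input table. Where the ratio falls strictly below 0.95 the enrollment
fallback activates: every beneficiary *born in that state-year* whose
Medicaid enrollment started no later than one day after birth becomes a
candidate. The born-in-that-state-year condition is an age-0 guard we added;
without it, any long-enrolled beneficiary whose enrollment started near their
own birth would flood the pool. A candidate found both ways is labelled
`code_based`. The comparison is made before the singleton exclusion because
multiple gestations cannot be separated in the benchmark counts.

## Matching variables

Four variables beyond state and dates are prepared for both pools:

* **residential ZIP** — from enrollment, normalized to 5 digits (9-digit
  ZIPs truncated), `00000` treated as missing;
* **facility ZIP** — each claim's provider NPI looked up in the registry
  table for the claim year; within a delivery's cluster window (or a
  newborn's post-birth week) the modal resolved ZIP wins, ties broken by
  earliest claim date, then lexicographically;
* **race/ethnicity** — harmonized to eight reporting categories;
  multiracial identities are blanked *in the matching key only* (recorded
  congruence between mothers and infants is poor there) while the reported
  value is kept for the representativeness table;
* **case ID** — blanked when empty, matching a sentinel pattern
  (all-zeros/all-nines by default), or held by more than 10 distinct
  beneficiaries in a state-year, which indicates a program-level rather than
  household-level identifier.

Keys are drawn from the enrollment record of the event year (delivery
midpoint year, birth year); when that year is absent, the nearest available
year is used, preferring the earlier year on ties. The year alignment is not
specified in the published method; nearest-year is the least-surprising
choice and is exercised by fixtures in the test suite. All cleaning steps are
idempotent, and per-variable missingness is tallied into an attribute for
run accounting.

## The matching algorithm

Matching proceeds through six phases of progressively weaker criteria, each
iterating through eight steps. Two constraints are *hard* in every cell:
the records must share a state, and the newborn's date of birth must lie in
the delivery window widened by the phase's tolerance (0, 1 or 2 days,
symmetric on both ends). Phases 1–3 additionally require a case ID present on
both sides and equal; phases 4–6 impose no case-ID condition at all (missing
and conflicting case IDs are both allowed — some states assign none, others
assign different numbers to parents and children). Within a phase, the eight
steps require the three remaining variables (residential ZIP, facility ZIP,
race/ethnicity) in decreasing subsets: all three, each pair, each single
variable, none. The order among equal-size subsets follows the variable
enumeration order; it is configurable, and any order is reproducible from a
schedule object.

A required variable matches only when it is **present on both sides and
equal** — missing never acts as a wildcard. The relaxation steps are the
mechanism for handling missing data; letting missing values match would
manufacture links exactly where the data are weakest.

Within a cell, all candidate pairs are formed from the current unmatched
pools and a pair is accepted only when both its delivery and its newborn
participate in exactly one candidate pair (mutual degree one). Acceptance is
simultaneous across the cell: degrees are computed before any removal, so
the result cannot depend on row order. Accepted records leave both pools
before the next cell. An optional fixed-point mode
(`pipeline_config(iterate_within_step = TRUE)`) re-evaluates uniqueness
within the cell after each acceptance pass until nothing changes; the
published description reads as a single pass, which is the default, and the
alternative exists for sensitivity analysis.

A mother with two deliveries contributes two independent matchable units;
the 270-day clustering gap guarantees their date windows (at most 7 days
wide, tolerance at most 2 days) can never both admit one newborn.

`run_matching()` uses keyed joins for the equality blocks and a non-equi join
for the date window. `brute_force_match()` implements the same semantics by
scoring every pair explicitly with no blocking; it exists purely as an
independent cross-check and the suite asserts exact link-set equality
(including phase/step attribution) across seeded random pools.

## The synthetic generator

Restricted claims data cannot ship with a package, so `synth_generate()`
builds a claims universe with known ground truth, emulating the structural
heterogeneity that motivates the design:

* per-state settings for whether household case IDs exist, the probability
  newborn care is billed under the mother, and code coverage;
* households with shared residential ZIPs and case IDs, facilities with an
  NPI-to-ZIP registry;
* mothers with one or two deliveries (second with probability 0.25, spaced
  300–700 days so true deliveries stay separable by the 270-day rule),
  delivery claims jittered up to 2 days after the true date;
* twins at 1.5% of deliveries, flagged with multiple-gestation codes;
* per-variable missingness (defaults 5% residential ZIP, 5% facility signal,
  10% race, 2% case ID), infants recorded with the mother's race 80% of the
  time and `Unknown/Other` otherwise, reflecting sparse newborn race
  recording;
* 10% additional newborns enrolled at birth whose mothers had no
  Medicaid-paid delivery (they must remain unlinked), 2% late-enrolled
  infants, and benchmark counts thinned by a 5% payer-misreport rate so the
  identified counts over-cover the benchmark, as real comparisons do.

These defaults were chosen once as plausible magnitudes for the documented
phenomena and are the package's standing study conditions; evaluation
regimes (for example the perfect-information regime with zero noise, unique
case IDs and full race agreement) are explicit configurations, not changed
defaults. All randomness flows from one seeded stream, so outputs are
byte-reproducible.

What the generator does **not** emulate: realistic marginal distributions of
codes, providers or geography; duplicate or contradictory enrollment rows;
clerical errors in identifiers; household structures beyond mother+infants;
migration between states. Passing tests therefore demonstrate the logic of
the pipeline under controlled structural noise, not performance on real
claims.

## Numerical and degenerate-input choices

* Dates are calendar dates; all arithmetic is in whole days.
* Cluster midpoints round down on odd spans.
* Window span is `end - start` days; the inclusive-count convention is a
  config switch.
* A benchmark count of zero makes the coverage ratio undefined and activates
  the fallback.
* Empty inputs yield empty outputs everywhere (no errors from empty pools,
  empty claim sets, or empty code lists except where a role is required).
* Facility-ZIP ties break by earliest claim date, then lexicographic ZIP.
* `accept_unique()` on an empty pair set returns an empty link set; tallies
  still cover all 48 cells.

## Problem sizes in the test and acceptance runs

The suite exercises the matcher against the exhaustive reference on pools of
50–80 records per side across dozens of seeds, the clustering oracle on up to
6 claims (exhaustive enumeration grows as the Bell numbers), statistical
checks of the generator at roughly 11,000 births, and the perfect-information
recovery at roughly 10,000 births across two states. These sizes give the
properties room to fail while keeping a full run in the low minutes on one
core; the algorithms themselves are join-based and scale to much larger
inputs.

## Known limitations

* The blocking keys are exact-equality comparisons; no string distances or
  probabilistic weights (a deliberate design of the underlying method).
* The "invalid ZIP" notion is syntactic (5 digits, not all zeros); a
  user-supplied valid-ZIP directory can be layered on by blanking keys before
  matching.
* The default code lists are small illustrative placeholders; real analyses
  must supply validated lists (published delivery lists run to ~100 codes).
* Managed-care status is pass-through: it appears in the representativeness
  table only if an enrollment `managed_care` column is supplied.
* Case-ID cleaning assumes household IDs are stable within a state-year;
  IDs that change yearly within a household reduce phase-1–3 yield but never
  create false links (uniqueness still binds).
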