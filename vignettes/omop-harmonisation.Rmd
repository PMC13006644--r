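---
title: "Harmonising longitudinal survey data into the OMOP CDM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising longitudinal survey data into the OMOP CDM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopsurvey)
```

## The problem and the model

Population mental-health studies collect repeated psychometric assessments
(PHQ-9, GAD-7, EPDS, DASS-21, CES-D, PCL-5, PSQ) from individuals nested in
households across data-collection waves. `omopsurvey` models that source
world as a five-table snowflake staging schema and transforms it into the
OMOP Common Data Model so OHDSI-style analytics (cohorts, characterisation,
incidence, pathways) apply. The transformation follows four conceptual
phases: prepare the environment and configuration; load staging data and
vocabularies; map and load the CDM tables in dependency order (location,
care site, provider, person, visit occurrence, then the event tables);
and run quality checks on the result.

Three commitments shape every module:

1. **Nothing is silently dropped.** Every nulled, excluded or remapped cell
   produces exactly one error-log entry, and every transformation step
   records `rows_in = rows_out + rows_excluded` in an execution summary.
   Placeholder identifiers are never invented for missing required keys;
   such rows are excluded and logged.
2. **Local semantics are preserved, not discarded.** Survey terms without a
   standard equivalent get minted local concepts with identifiers above
   2,000,000,000, kept in a dedicated vocabulary. We deliberately deviate
   from the THEMIS convention of confining custom concepts to
   `*_source_concept_id`: local concepts are standard-flagged (`S`) and used
   directly in `*_concept_id` fields, because that is what keeps them
   visible to cohort tooling. Semantic links always come in inverse pairs
   (`Maps to`/`Maps from`, `Has answer`/`Is an answer of`).
3. **Determinism end to end.** All randomness is seeded; the wall clock is
   never read for data content (the reference "today" and the manifest
   timestamp are config values); id assignment is by deterministic
   enumeration of sorted source identifiers. Two runs with the same config
   are byte-identical, manifest included.

## The synthetic-data generator

Individual-level survey data of this kind are access-restricted, so the
package ships a generator whose output has known ground truth. It emulates:

* a roster of `n_individuals` assigned uniformly to `n_households`, with
  sex (60/40 female/male), birth dates uniform over ages 18–70 at the first
  wave, and race/ethnicity/marital codes with realistic skews;
* `n_waves` waves at a fixed interval (default 182 days) from a configured
  first wave date — the source schedule is study-specific, so it is a
  config value, not a hard-coded calendar;
* per individual × wave × instrument, one response per item drawn from a
  fixed categorical distribution skewed toward low severity
  (weights 0.45/0.25/0.15/0.09/0.06 truncated to the item range and
  renormalised) — real severity distributions vary by setting, but the
  weights must be explicit for reproducibility;
* independent item missingness (default 5%) and, optionally, demographic
  missingness (default 0).

It does **not** emulate psychometric factor structure, within-person
trajectory correlation, informative attrition, or household clustering of
outcomes. Passing tests on this data therefore demonstrates the
*engineering* correctness of the pipeline — referential closure, audit
conservation, detection of planted violations — not the epidemiological
realism of any estimate computed from it.

`inject_errors()` plants five corruption types and returns a ledger keyed by
the corrupted source cell: shifted birth dates (future, or past the first
responded wave so events precede birth), nulled individual identifiers,
unmappable category codes, and out-of-range item values. Counts are
requested per rule; individual-level rules draw disjoint targets so the
ledger stays unambiguous.

## Instrument scoring

Item codings default to the standard published ranges (0–3 for PHQ-9,
PHQ-5, GAD-7, EPDS, DASS-21 and CES-D items; 0–4 for PCL-5; 1–4 for the
PSQ). Totals are plain sums except DASS-21, which uses the conventional
doubling (`sum_times_two`) so short-form scores are comparable with the
full-length scale; its depression/anxiety/stress subscales carry the
standard item assignments. The default completeness policy is strict: any
missing item leaves the total absent (no prorating), because survey
pipelines should not impute silently; prorating (≥ 80% answered, mean
imputation) is an explicit opt-in. An out-of-range item is fatal in direct
scoring; the ETL instead opts into `treat_missing` so corrupted values flow
into the CDM, where the plausibility checks are the designated detector.
Severity thresholds are configuration, not constants: the default condition
rules (PHQ-9 ≥ 10 → depressive disorder 440383; GAD-7 ≥ 10 → anxiety
disorder 442077) use the conventional moderate cut-points and can be
replaced or disabled.

## Mapping and domain routing

Mappings are an explicit curated input — expert review produces them, code
only applies them. Routing follows the OHDSI definitions: quantitative
variables with a defined unit or scale go to Measurement; questionnaire
content without intrinsic units goes to Observation; Condition routing
requires an explicit diagnosis flag in the variable metadata, since nothing
in a variable's shape reveals that it is a diagnosis. Unmapped and
deprecated codes go to a review queue with a reason; coverage is the mapped
fraction of distinct variables, defined as 1 for an empty study (the
vacuous case must not divide by zero). A convenience exact-name matcher
exists but is off by default — name equality is not semantic equivalence.

For synthetic studies, `build_study_vocabulary()` plays the role of the
expert: it mints one local concept per variable, answer concepts (paired
with `Has answer`) per categorical covariate level, and one Measurement
concept per instrument's composite score, carried in the mapping table
under the pseudo-variable key `<instrument>__total`.

## ETL numerical and structural choices

* CDM dialect: the OMOP 5.x column set for the tables emitted; `care_site`
  and `provider` are emitted header-only to honour the dependency order.
* One visit per (individual, wave) with at least one response;
  `visit_start = visit_end = wave_date`.
* `person_id` (and all other surrogate ids) by deterministic enumeration of
  the sorted source identifier; the source id is retained in
  `person_source_value` for traceability.
* Date cleaning: birth dates after the reference date are nulled and
  logged, then the person is excluded for lacking a mandatory birth year;
  event dates before birth or after the reference date are nulled, logged,
  and the record excluded for lacking a mandatory date. Each action gets
  its own log entry, so a cascade is fully visible in the audit.
* Demographic codes run through explicit maps; absent or unknown codes
  coalesce to concept 0 ("no matching concept") with a `remapped` log
  entry. All `*_type_concept_id` fields take one uniform configured value
  (default 32862, survey).
* Unknown categorical response codes keep their row but take
  `value_as_concept_id = 0` with a `remapped` entry — the row is data, the
  code is the problem.

## Quality checks and the reconciliation accounting

The packaged suite (≥ 30 checks; 67 with a registry and plan supplied) is a
representative Kahn-framework engine, not a re-implementation of the
1,500+ checks of the full DQD catalogue. Verification checks are
CDM-internal (non-nullity, key uniqueness, foreign keys, date typing,
temporal consistency); Validation checks consult the vocabulary registry or
config-declared expectations (concept resolution, domain agreement,
standard flags, demographic membership, instrument score/item ranges). All
thresholds default to 0 — the strictest reading of "violation fraction
versus predefined threshold". `NOT_APPLICABLE` results (empty tables) are
excluded from pass-rate denominators so empty tables are not rewarded.
Pass percentages are rounded to whole percents; an empty cell renders
blank.

A single corrupted source cell can cascade into several downstream log rows
(one shifted birth date invalidates a visit and every event on it). The
reconciliation in `reconcile_injections()` therefore accounts at the level
of the injected source key: a ledger entry is accounted when at least one
ETL-log entry or QC violating key traces back to it, and cleaned/detected
are combined as a union so nothing is double-counted. Under this accounting
the invariant is exact: per rule, accounted equals injected. Traceability
rests on the `*_source_value` columns, which carry the
`individual::wave::variable` key end to end.

## Analytics conventions

* Earliest-event cohorts: one membership per person at the first qualifying
  event; same-date ties resolve to the smallest record id (pure tie-break —
  the index date is unaffected).
* Person-time uses 365.25 days per year; days at risk are counted
  inclusively from the window start, and a case's time stops at the first
  in-window outcome. An outcome before the window start is not a case. The
  observation window is the span of a person's recorded events — survey
  data have no enrolment table, so the event span is the only defensible
  surrogate.
* Age at index uses year, month and day of birth where present; missing
  month/day is taken as July 1 (the standard mid-year convention).
* Pathway ties collapse into unordered sets (`{A+B}`) rather than being
  given a fabricated order.
* Degenerate denominators (zero person-years, empty cohorts) yield `NA`
  rates, rendered n/a, never `Inf` or `NaN`.

## Problem sizes and verification strategy

The test suite verifies the audit and reconciliation invariants on a
1,000-person, 3-wave study with 50 planted errors, the quality rollup on a
60-person clean study, the earliest-event law on 100 randomly generated
cohort definitions, and incidence against an independent per-person
day-iteration oracle (exact for persons and cases, 10⁻⁹ for rates) on
studies of up to 150 persons. These sizes were chosen to exercise every
cascade path (multi-wave corruption, orphaned events, incomplete
administrations) while keeping the full suite fast enough to run on every
change. The acceptance script re-runs the same computations from scratch at
the same sizes.

## Known limitations

* The generator's independence assumptions (items, missingness, waves) make
  detection problems easier than in real data, where errors cluster.
* Only the CDM tables a survey pipeline populates are emitted; drug, death
  and procedure domains, observation periods, and live database loading are
  out of scope.
* The check engine covers row-level predicates; distributional profiling
  (outlier scans, temporal trend checks) is not implemented.
* Local-concept curation workflows (review, promotion to standard
  vocabularies) are represented only by the review queue.
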