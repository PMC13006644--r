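# omopsurvey

Longitudinal mental-health surveys — household panels, postpartum cohorts,
health-and-demographic-surveillance rounds — arrive as heterogeneous,
snowflake-shaped relational data: households, individuals, data-collection
waves, instruments, and item responses. Making such studies comparable and
analysable with the OHDSI toolchain requires migrating them into the OMOP
Common Data Model, minting local vocabulary concepts for the many survey
terms that have no standard equivalent, and proving — with an audit trail —
that nothing was silently lost or distorted on the way.

`omopsurvey` is a desk-scale, fully reproducible R toolkit for exactly that
pipeline. It is aimed at health-data engineers and epidemiologists who need
to prototype, test and teach staging-to-OMOP harmonisation without access to
restricted individual-level data: every component runs end to end on
synthetic studies whose ground truth is known.

## What it provides

* **Staging model** (`staging_bundle`, `load_staging`, `write_staging`) — a
  file-backed snowflake schema (households / individuals / waves / variables
  / responses) with strict referential closure: dangling rows are excluded
  and counted, never repaired.
* **Synthetic studies** (`study_config`, `generate_study`) — multi-wave
  survey data with standard psychometric instruments (PHQ-9, GAD-7, EPDS,
  DASS-21, CES-D, PCL-5, PSQ) and controlled missingness, plus
  `inject_errors()` which plants known corruptions (future birth dates,
  events before birth, null identifiers, unmappable codes, out-of-range
  items) and returns a ground-truth ledger.
* **Vocabulary extension** (`concept_registry`, `mint_local_concept`) —
  local concepts minted sequentially above 2,000,000,000 (the first is
  2,000,000,001), standard-flagged so they work directly in `*_concept_id`
  fields; every `Maps to` / `Has answer` relationship is stored with its
  inverse. Athena-style tab-separated vocabulary I/O.
* **Mapping** (`compile_mapping_plan`) — curated variable→concept mapping
  with OHDSI domain routing (quantitative + unit ⇒ Measurement, otherwise
  Observation; explicit flags ⇒ Condition), a review queue for unmapped or
  deprecated codes, and a coverage statistic.
* **ETL** (`run_etl`) — dependency-ordered population of the CDM tables
  (location → person → visit_occurrence → measurement / observation /
  condition_occurrence), instrument scoring to Measurement, item responses
  to Observation, screening-threshold condition derivation, and a complete
  audit: an error log with one entry per nulled/excluded/remapped cell and
  an execution summary in which every step satisfies
  `rows_in = rows_out + rows_excluded`.
* **Quality checks** (`default_check_suite`, `run_checks`) — a declarative
  Kahn-framework engine (conformance / completeness / plausibility, each as
  verification or validation) with PASS/FAIL at configurable thresholds and
  a classic pass-rate rollup; `reconcile_injections()` proves that every
  planted corruption is either cleaned by the ETL or detected by the checks.
* **Analytics** (`build_cohort`, `characterize_cohort`, `incidence_rates`,
  `pathway_sequences`) — earliest-event cohorts (persons and episodes
  one-to-one), demographic characterisation, incidence per 1,000
  person-years with `rate = 1000 · cases / person-years` and
  `person-years = Σ days-at-risk / 365.25`, and event-cohort pathway
  sequencing with tie collapsing.
* A thin command-line driver (`inst/cli/omopsurvey`) chaining the phases
  `synth | vocab-build | map | etl-run | qc-run | cohort | report` from one
  YAML config, with a reproducibility manifest of seeds and file digests.

## Worked example

```r
library(omopsurvey)

bundle <- generate_study(study_config(n_individuals = 100, n_waves = 2, seed = 42))
built  <- build_study_vocabulary(bundle)
plan   <- compile_mapping_plan(bundle, built$registry, built$mapping)
glance(plan)
#>   n_variables n_mapped n_review coverage
#> 1          18       18        0        1

cdm <- run_etl(bundle, plan, built$registry, etl_config())
cdm
#> <cdm_bundle> synthetic_study
#>   location                    40 rows
#>   person                     100 rows
#>   visit_occurrence           200 rows
#>   measurement                249 rows
#>   observation               3417 rows
#>   condition_occurrence        51 rows
#>   error_log: 0 entries; execution_summary: 8 steps

report <- run_checks(cdm, built$registry,
  default_check_suite(built$registry, plan, bundle$variables))
glance(report)
#>   n_checks pass fail not_applicable pct_pass
#> 1       67   67    0              0      100
```

All 18 staging variables map (coverage 1.0); 100 individuals over 2 waves
become 200 wave-visits; 249 composite scores land in Measurement (a few
administrations are incomplete under 5% item missingness and are not
scored); the 3,417 item and covariate responses land in Observation; 51
screening-positive administrations (PHQ-9 or GAD-7 total ≥ 10) derive
condition rows. On clean data the error log is empty and all 67 quality
checks pass.

Downstream, earliest-event cohorts and incidence:

```r
dep <- cohort_definition("depression_screen", "condition_occurrence", 440383)
anx <- cohort_definition("anxiety_screen",    "condition_occurrence", 442077)
incidence_rates(cdm, dep, anx, tar_start_offset = 1)
#>   target_cohort_id  outcome_cohort_id persons_at_risk cases person_years
#> 1 depression_screen    anxiety_screen              17     0      8.47091
#>   cases_per_1000_persons rate_per_1000_py
#> 1                      0                0
```

`autoplot()` methods exist for quality reports, concept classifications and
incidence results; `tidy()` / `glance()` for plans, reports and CDM bundles.

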