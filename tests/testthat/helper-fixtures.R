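# Shared fixtures, built once per test run and cached: a small clean study
# pipeline and a corrupted one with a known injection ledger.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

clean_pipeline_fixture <- function() {
  cached_fixture("clean_pipeline", {
    sc <- study_config(
      n_individuals = 60, n_households = 25, n_waves = 3, seed = 401,
      item_missingness = 0.05
    )
    bundle <- generate_study(sc)
    built <- build_study_vocabulary(bundle)
    plan <- compile_mapping_plan(bundle, built$registry, built$mapping)
    cdm <- run_etl(bundle, plan, built$registry, etl_config())
    suite <- default_check_suite(built$registry, plan, bundle$variables)
    report <- run_checks(cdm, built$registry, suite)
    list(config = sc, bundle = bundle, registry = built$registry,
      mapping = built$mapping, plan = plan, cdm = cdm, suite = suite,
      report = report)
  })
}

corrupt_pipeline_fixture <- function() {
  cached_fixture("corrupt_pipeline", {
    sc <- study_config(
      n_individuals = 120, n_households = 40, n_waves = 3, seed = 402
    )
    bundle <- generate_study(sc)
    spec <- error_spec(
      future_birth_dates = 4, event_before_birth = 3, null_required_ids = 3,
      unmapped_codes = 5, out_of_range_items = 6, seed = 77
    )
    inj <- inject_errors(bundle, spec, reference_date = sc$reference_date)
    built <- build_study_vocabulary(inj$bundle)
    plan <- compile_mapping_plan(inj$bundle, built$registry, built$mapping)
    cdm <- run_etl(inj$bundle, plan, built$registry, etl_config())
    suite <- default_check_suite(built$registry, plan, inj$bundle$variables)
    report <- run_checks(cdm, built$registry, suite)
    list(config = sc, clean_bundle = bundle, bundle = inj$bundle,
      ledger = inj$ledger, registry = built$registry, plan = plan,
      cdm = cdm, report = report)
  })
}

demo_config_path <- function() {
  p <- system.file("extdata", "demo_config.yaml", package = "omopsurvey")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata", "demo_config.yaml")
}
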