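# One shared default fixture + pipeline run reused by the fixture,
# pipeline and acceptance tests (generation is deterministic at the fixed
# seed, so sharing does not couple the tests).
fx_dir <- file.path(tempdir(), "funsnp_fixture")
fx_out <- file.path(tempdir(), "funsnp_fixture_out")
fx_truth <- suppressMessages(generate_fixture(fixture_config(seed = 7), fx_dir))
fx_summary <- suppressWarnings(suppressMessages(
  run_pipeline(file.path(fx_dir, "config.yaml"), fx_out, force = TRUE)))
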