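# In-code fixtures for format and diff tests.

ri_test_doc <- function(seed = 1, n_modules = 4, n_processors = 2) {
  generate_fixture(fixture_spec(seed, n_modules, n_processors))$a
}

ri_test_pair <- function(seed, perturbations) {
  generate_fixture(fixture_spec(seed, n_modules = 5, n_processors = 2,
                                perturbations = perturbations))
}

# fresh lifecycle state for in-process activation tests
ri_local_state <- function(env = parent.frame()) {
  runinfo:::.ri_reset()
  withr::defer(runinfo:::.ri_reset(), envir = env)
}
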