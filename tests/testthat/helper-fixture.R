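# one default-condition study fixture, simulated once per test session and
# shared by the tests that need realistic data
.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_study(sim_config(seed = 42))
  }
  .fixture_env$sim
}
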