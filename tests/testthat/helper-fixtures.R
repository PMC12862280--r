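# Shared small simulated fixtures, built once per test run.

small_config <- function(seed = 11, ...) {
  sim_config(n_rows = 8, n_cols = 8, rho = 0.5,
             planted_blocks = list(planted_block(c(2, 4), c(2, 4))),
             n_properties_per_tract = 20, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_tract_data <- function() {
  if (is.null(.fixture_env$td)) {
    .fixture_env$td <- synthesize_tracts(small_config())
    .fixture_env$tab <- compute_indices(.fixture_env$td)
  }
  list(td = .fixture_env$td, tab = .fixture_env$tab)
}
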