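# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# small-grid spec: fast to rasterize, large enough for stable texture
small_spec <- function(n_per_class = 8L, master_seed = 5L) {
  cohort_spec(n_per_class = n_per_class,
              grid = list(shape = c(48L, 48L, 20L), spacing = c(2.5, 2.5, 6)),
              master_seed = master_seed)
}

small_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    .fixture_env$phantom <- generate_kidney_phantom(
      small_spec(), "UPD+IC1", 18, 777, "FIX1")
  }
  .fixture_env$phantom
}
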