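# Shared fixtures: bundles are generated in code, never stored on disk.

# Small, fast bundle for structural tests (full-size bundles are used where
# a test checks planted-truth recovery).
small_params <- function(seed = 1, ...) {
  sim_params(n_sites = 10, plots_per_site = 4, n_otus = 80,
             n_plant_species = 25, sequencing_depth = 2000, seed = seed, ...)
}

# Memoised default-parameter bundle, reused across test files.
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 1) {
  key <- paste0("b", seed)
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- simulate_mountain(sim_params(seed = seed))
  .bundle_cache[[key]]
}

# Null-gradient parameters: no fault effect anywhere (used for type-I
# calibration).
null_params <- function(seed) {
  sim_params(pool_mixing = 0, evenness_step = 0, geo_step = 0,
             fun_break_scale = 0, seed = seed)
}

site_elev_of <- function(bundle) {
  tapply(bundle$samples$elevation, bundle$samples$site_id, unique)
}

expect_within_one_spacing <- function(estimate, truth, spacing = 180) {
  expect_lte(abs(estimate - truth), spacing)
}
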