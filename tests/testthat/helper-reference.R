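# Shared fixtures computed once per test run. The reference analysis is
# the expensive piece (full pipeline on the shipped synthetic study);
# tests that need it share a single memoised run.

.ref_cache <- new.env(parent = emptyenv())

get_reference_dataset <- function() {
  if (is.null(.ref_cache$dataset)) {
    .ref_cache$dataset <- reference_dataset()
  }
  .ref_cache$dataset
}

get_reference_result <- function() {
  if (is.null(.ref_cache$result)) {
    ds <- get_reference_dataset()
    .ref_cache$result <- run_pipeline(ds$fixes, ds$map, ds$temps,
                                      pipeline_config(seed = 1L))
  }
  .ref_cache$result
}

# a small but complete simulated study for fast end-to-end tests
small_dataset <- function(seed = 11L) {
  cfg <- sim_config(
    seed = seed, n_females = 4L, n_males = 4L,
    extent = c(length = 2500, width = 374),
    n_rounds = 3L,
    association_plan = list(
      list(pair_class = "FM", habitat = "TG", rounds = c(1L, 2L),
           strength = 0.85, n_pairs = 1L))
  )
  map <- generate_habitat_map(cfg)
  sim <- simulate_trajectories(cfg, map)
  temps <- reference_temperatures()
  list(fixes = sim$fixes, map = map, temps = temps, truth = sim$truth,
       config = cfg)
}

small_pipeline_config <- function(seed = 1L) {
  pipeline_config(seed = seed, radii = seq(50, 500, by = 50),
                  k_range = 2:5, restarts = 5L,
                  phases = som_phases(rough_iter = 40L, fine_iter = 10L),
                  dist_min_f = 10L, dist_min_m = 10L,
                  cooc_min_f = 10L, cooc_min_m = 10L)
}
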