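# Shared fixtures.  Expensive objects are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

# full-size paired experiment shared by the acceptance tests
acceptance_experiment <- function() {
  if (is.null(.cache$experiment)) {
    .cache$experiment <- run_paired_experiment(
      lengths = c(1, 2, 4, 8, Inf), repetitions = 100, seed = 101)
  }
  .cache$experiment
}

# default 10-participant synthetic dataset, analyzed end to end
acceptance_dataset <- function() {
  if (is.null(.cache$dataset)) {
    cfg <- generator_config(seed = 1)
    ds <- generate_dataset(cfg)
    .cache$dataset <- list(cfg = cfg, truth = ds$truth,
                           measures = analyze_dataset(ds$trials))
  }
  .cache$dataset
}

# small fingertip for unit tests (fewer units than the default patch)
small_fingertip <- function(seed = 11) {
  build_fingertip(seed, config = fingertip_config(patch_width = 10,
                                                  patch_height = 10))
}

# hand-built uniform-variant population: single-element units at given
# element positions (mm) with given radii, on the default 20 x 20 patch
toy_population <- function(x, y, radius) {
  n <- length(x)
  units <- tibble::tibble(id = seq_len(n), x = x, y = y, rf_radius = radius)
  structure(list(
    units = units,
    elements = tibble::tibble(unit_id = units$id, x = x, y = y,
                              radius = radius),
    variant = "uniform", config = fingertip_config(), seed = 0L
  ), class = "fingertip_model")
}

# one synthetic trial plus ground truth, with the RNG seeded
make_trial <- function(edge_length = 8, initial_orientation = -30,
                       cfg = generator_config(noise = FALSE), seed = 5,
                       final = NULL) {
  set.seed(seed)
  out <- sample_trial_outcome(edge_length, initial_orientation, cfg)
  if (!is.null(final)) out$final_orientation <- final
  synthesize_traces(out$final_orientation,
                    meta = list(edge_length = edge_length,
                                initial_orientation = initial_orientation,
                                participant = 1L, trial = 1L),
                    cfg = cfg)
}
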