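# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code; no image files ship with the package.

.fixtures <- new.env(parent = emptyenv())

# A small but complete experiment: 2 tiles, 6 hourly frames, ~90 droplets.
small_experiment <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- generator_config(tile_px = 256, n_tiles = 2, n_timepoints = 6,
                            killer_prob = 0.5, seed = 101)
    .fixtures$small <- generate_experiment(cfg)
  }
  .fixtures$small
}

small_pipeline <- function() {
  if (is.null(.fixtures$small_pl)) {
    .fixtures$small_pl <- run_pipeline(small_experiment())
  }
  .fixtures$small_pl
}

# The validation-scale experiment: >= 1,000 droplets, 11 hourly frames,
# default dye/noise settings, fixed seed. Expensive; built once.
validation_experiment <- function() {
  if (is.null(.fixtures$big)) {
    .fixtures$big <- generate_experiment(generator_config(seed = 1))
  }
  .fixtures$big
}

validation_pipeline <- function() {
  if (is.null(.fixtures$big_pl)) {
    .fixtures$big_pl <- run_pipeline(validation_experiment())
  }
  .fixtures$big_pl
}

# Noise-free single-tile render for the detection oracle tests.
clean_tile_experiment <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- generator_config(tile_px = 512, n_tiles = 1, n_timepoints = 2,
                            noise_sd = 0, jitter_sd_px = 0, mover_fraction = 0,
                            seed = 7)
    .fixtures$clean <- generate_experiment(cfg)
  }
  .fixtures$clean
}
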