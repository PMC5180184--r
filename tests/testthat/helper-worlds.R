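# Shared fixtures: memoised synthetic worlds so expensive builds run once
# per test session.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, config_fn) {
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- build_world(config_fn())
  }
  .world_cache[[key]]
}

# The stated default world (seed 42, 14 models, 24 x 36 grid, 2000-2011).
default_world <- function() cached_world("default", world_config)

# A small world for structural tests where statistical power is not the
# point.
small_world <- function() {
  cached_world("small", function() {
    world_config(nlat = 10, nlon = 15, n_models = 5, seed = 7)
  })
}

# Scores of the default world against SIF (spatial mode), memoised.
default_scores <- function() {
  if (is.null(.world_cache[["default_scores"]])) {
    w <- default_world()
    .world_cache[["default_scores"]] <-
      ensemble_scores(w$models, w$sif, w$biomes,
                      training_years = w$config$training_years)
  }
  .world_cache[["default_scores"]]
}

# Population (divide-by-N) standard deviation, matching the package's
# IAV convention.
sd_for_test <- function(x) sqrt(mean((x - mean(x))^2))

# Flat little grid near the equator where cos-latitude weights are nearly
# equal; handy for hand-computed oracles.
flat_grid <- function(nlat = 2, nlon = 3) {
  grid_spec(seq(-0.5, 0.5, length.out = nlat),
            seq(0, 2, length.out = nlon))
}

# Build an annual cube from a [time, lat, lon] array on a flat grid.
flat_cube <- function(values, years = NULL, units = "g C m-2 yr-1") {
  d <- dim(values)
  if (is.null(years)) years <- 2000 + seq_len(d[1]) - 1
  grid <- grid_spec(seq(-0.5, 0.5, length.out = d[2]),
                    seq(0, 0.1 * (d[3] - 1), length.out = d[3]))
  gridded_cube(values, years, grid, units = units, freq = "annual")
}
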