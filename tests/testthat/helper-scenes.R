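# Shared fixtures: small scenes and simple tiles, built in code.

# a bare tile on a metric-degree grid at the equator: dx chosen so one pixel
# is `pixel_m` meters across
tile_m <- function(values, pixel_m = 12, lon0 = 0, lat0 = 0, ...) {
  d <- pixel_m / mangroveheight:::M_PER_DEG
  raster_tile(values, lon0, lat0, dx = d, dy = d, ...)
}

# all stochastic structure switched off: truth passes through the whole
# pipeline unchanged
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(water_fraction = 0, artifact_count = 0, dem_noise_sd_m = 0,
         rh_noise_sd_m = 0, geolocation_jitter_sd_m = 0,
         contamination_fraction = 0, als_noise_sd_m = 0),
    list(...))
  do.call(scene_config, args)
}

# the filter-accounting fixture: 1000 shots, 10% single-criterion
# contamination, everything else guaranteed to pass (no noise, no jitter,
# no water so footprints always cover full pixels)
accounting_config <- function(seed = 2024L) {
  scene_config(tile_size_px = 120, n_shots = 1000,
               contamination_fraction = 0.10, water_fraction = 0,
               artifact_count = 0, dem_noise_sd_m = 0, rh_noise_sd_m = 0,
               geolocation_jitter_sd_m = 0, als_noise_sd_m = 0, seed = seed)
}

# synthetic footprint-pair tables for the calibration stage
sqrt_law_pairs <- function(n, a = 1.02, b = 0.33, sqrt_noise_sd = 0,
                           x_max = 55, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0.5, x_max)
  s <- a * sqrt(x) + b + rnorm(n, sd = sqrt_noise_sd)
  tibble::tibble(tdx_max = x, rh98 = s^2)
}
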