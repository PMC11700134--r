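#' Synthetic scene configuration
#'
#' Parameters of the synthetic mangrove scene generator. The generator
#' emulates the statistical structure the pipeline assumes: a smooth true
#' canopy height field over a mangrove extent cut by water channels, a 12 m
#' InSAR-like DEM (truth + geoid undulation + noise + sparse gross
#' artifacts), a co-located smooth 30 m reference DEM, a backscatter time
#' stack with persistently low returns over water, lidar footprints sampling
#' the truth with vertical noise, geolocation jitter and a contaminated
#' fraction failing quality flags, and a 1 m airborne canopy height model of
#' the same truth.
#'
#' @param tile_size_px side length of the 12 m grid (pixels).
#' @param origin_lon_lat upper-left corner (degrees, lon then lat).
#' @param truth_smoothness correlation length of the truth field (pixels).
#' @param height_range `c(min_m, max_m)` of land canopy heights, within
#'   \[0, 60\] m.
#' @param water_fraction target fraction of the scene carved into water
#'   channels, in \[0, 1\].
#' @param artifact_count number of gross DEM artifact patches.
#' @param artifact_magnitude_m height offset of artifact patches (m, > 30 so
#'   the reference-DEM rule can detect them).
#' @param n_shots number of lidar footprints.
#' @param rh_noise_sd_m Gaussian sd of RH98 vertical noise (m).
#' @param geolocation_jitter_sd_m isotropic Gaussian sd of the reported
#'   footprint location around the true one (m).
#' @param contamination_fraction fraction of shots given one failing quality
#'   field each, in \[0, 1\].
#' @param undulation_m mean geoid undulation (m); the generated undulation
#'   field adds a gentle east-west gradient around it.
#' @param dem_noise_sd_m per-pixel Gaussian height noise of the 12 m DEM (m).
#' @param als_noise_sd_m per-pixel noise of the 1 m airborne CHM (m).
#' @param stack_layers number of backscatter layers in the time stack.
#' @param seed integer; fixes all randomness (identical config, identical
#'   scene, bit for bit).
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(tile_size_px = 120,
                         origin_lon_lat = c(-50.0, 2.0),
                         truth_smoothness = 20,
                         height_range = c(1, 50),
                         water_fraction = 0.10,
                         artifact_count = 3,
                         artifact_magnitude_m = 90,
                         n_shots = 2000,
                         rh_noise_sd_m = 2,
                         geolocation_jitter_sd_m = 10,
                         contamination_fraction = 0.10,
                         undulation_m = 15,
                         dem_noise_sd_m = 1,
                         als_noise_sd_m = 0.5,
                         stack_layers = 10,
                         seed = 42L) {
  chk <- function(ok, field, msg) if (!ok) stop(sprintf("invalid %s: %s", field, msg))
  chk(tile_size_px >= 20, "tile_size_px", "must be >= 20")
  chk(length(origin_lon_lat) == 2 && all(is.finite(origin_lon_lat)),
      "origin_lon_lat", "must be two finite degrees")
  chk(truth_smoothness > 0, "truth_smoothness", "must be > 0")
  chk(length(height_range) == 2 && height_range[1] >= 0 &&
        height_range[2] <= 60 && height_range[1] < height_range[2],
      "height_range", "must be increasing and within [0, 60]")
  chk(water_fraction >= 0 && water_fraction <= 1, "water_fraction", "must be in [0, 1]")
  chk(artifact_count >= 0 && artifact_count == round(artifact_count),
      "artifact_count", "must be a nonnegative integer")
  chk(artifact_count == 0 || artifact_magnitude_m > 30,
      "artifact_magnitude_m", "must be > 30 m")
  chk(n_shots > 0, "n_shots", "must be > 0")
  chk(rh_noise_sd_m >= 0, "rh_noise_sd_m", "must be >= 0")
  chk(geolocation_jitter_sd_m >= 0, "geolocation_jitter_sd_m", "must be >= 0")
  chk(contamination_fraction >= 0 && contamination_fraction <= 1,
      "contamination_fraction", "must be in [0, 1]")
  chk(dem_noise_sd_m >= 0, "dem_noise_sd_m", "must be >= 0")
  chk(als_noise_sd_m >= 0, "als_noise_sd_m", "must be >= 0")
  chk(stack_layers >= 1, "stack_layers", "must be >= 1")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  structure(as.list(environment())[names(formals(scene_config))],
            class = "scene_config")
}

# Separable Gaussian smoothing with edge renormalization (kernel mass
# inside the grid rescaled to 1), so smoothing preserves constants.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  smooth_rows <- function(mat) {
    n <- nrow(mat)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- max(1, i - r):min(n, i + r)
      w <- k[idx - i + r + 1]
      K[i, idx] <- w / sum(w)
    }
    K %*% mat
  }
  t(smooth_rows(t(smooth_rows(m))))
}

# Meandering water channels as lateral random walks across the grid.
carve_channels <- function(n, water_fraction) {
  water <- matrix(FALSE, n, n)
  if (water_fraction <= 0) return(water)
  width <- 3L
  n_channels <- max(1L, round(water_fraction * n / width))
  half <- width %/% 2
  for (ch in seq_len(n_channels)) {
    row <- sample.int(n, 1)
    for (col in seq_len(n)) {
      rows <- max(1, row - half):min(n, row + half)
      water[rows, col] <- TRUE
      row <- min(n, max(1, row + sample(c(-1L, 0L, 1L), 1)))
    }
  }
  water
}

#' Generate a complete synthetic mangrove scene
#'
#' See [scene_config()] for what is emulated. Rerunning with the same config
#' (same seed) is bit-identical.
#'
#' @param config a [scene_config()].
#' @return a `synthetic_scene` list with elements `truth_chm_12m`, `tdx_dem`
#'   (ellipsoidal), `undulation`, `ref_dem_30m` (geoid), `backscatter_stack`,
#'   `mangrove_extent` (25 m grid), `eez_polygons`, `eez_labels` (12 m),
#'   `water_mask_12m` (the generator's own channel mask, for reference),
#'   `artifact_mask`, `als_chm_1m`, `shots` (tibble) and `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  n <- config$tile_size_px
  lon0 <- config$origin_lon_lat[1]; lat0 <- config$origin_lon_lat[2]
  dy12 <- 12 / M_PER_DEG
  dx12 <- 12 / (M_PER_DEG * cos(lat0 * pi / 180))

  # smooth positive truth field rescaled to height_range
  raw <- gauss_smooth(matrix(stats::rnorm(n * n), n, n), config$truth_smoothness)
  lo <- config$height_range[1]; hi <- config$height_range[2]
  rng <- range(raw)
  truth <- lo + (raw - rng[1]) / (rng[2] - rng[1]) * (hi - lo)

  water <- carve_channels(n, config$water_fraction)
  # canopy tapers toward channels (fringe stands are shorter)
  if (any(water)) {
    land_frac <- gauss_smooth((!water) * 1, 1.5)
    truth <- truth * pmin(1, 1.25 * land_frac)
    truth <- pmax(truth, lo)
  }
  truth[water] <- NA_real_
  truth_tile <- raster_tile(truth, lon0, lat0, dx12, dy12, vdatum = "geoid")

  # DEM surface: canopy top over land, 0 (water level) in channels
  surface <- truth
  surface[water] <- 0

  und <- matrix(config$undulation_m, n, n) +
    outer(rep(1, n), seq(-1, 1, length.out = n))  # gentle E-W gradient, +-1 m
  und_tile <- raster_tile(und, lon0, lat0, dx12, dy12)

  noise <- if (config$dem_noise_sd_m > 0)
    matrix(stats::rnorm(n * n, sd = config$dem_noise_sd_m), n, n) else 0

  artifact <- matrix(FALSE, n, n)
  if (config$artifact_count > 0) {
    radius <- 3
    centers <- matrix(numeric(0), 0, 2)
    guard <- 0
    while (nrow(centers) < config$artifact_count && guard < 10000) {
      guard <- guard + 1
      cand <- c(sample((radius + 2):(n - radius - 1), 1),
                sample((radius + 2):(n - radius - 1), 1))
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - cand)^2))) > 2 * radius + 3)
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < config$artifact_count)
      stop("could not place disjoint artifact patches; reduce artifact_count")
    for (k in seq_len(nrow(centers))) {
      rr <- outer(seq_len(n) - centers[k, 1], rep(1, n))
      cc <- outer(rep(1, n), seq_len(n) - centers[k, 2])
      artifact <- artifact | (rr^2 + cc^2 <= radius^2)
    }
  }
  tdx <- surface + und + noise + artifact * config$artifact_magnitude_m
  tdx_tile <- raster_tile(tdx, lon0, lat0, dx12, dy12, vdatum = "ellipsoid")

  # 30 m reference DEM: block statistics of the surface, geoid-referenced
  dy30 <- 30 / M_PER_DEG
  dx30 <- 30 / (M_PER_DEG * cos(lat0 * pi / 180))
  n30r <- ceiling(n * dy12 / dy30); n30c <- ceiling(n * dx12 / dx30)
  ridx <- pmin(n30r, floor((lat0 - y_centers(truth_tile)) / dy30) + 1L)
  cidx <- pmin(n30c, floor((x_centers(truth_tile) - lon0) / dx30) + 1L)
  cell <- (rep(cidx, each = n) - 1L) * n30r + rep(ridx, times = n)
  ref <- matrix(NA_real_, n30r, n30c)
  sums <- tapply(as.vector(surface), cell, mean)
  ref[as.integer(names(sums))] <- sums
  ref_tile <- raster_tile(ref, lon0, lat0, dx30, dy30, vdatum = "geoid")

  # backscatter stack: persistently low returns over water
  stack <- lapply(seq_len(config$stack_layers), function(i) {
    v <- matrix(-8 + stats::rnorm(n * n, sd = 2), n, n)
    nw <- sum(water)
    if (nw) v[water] <- -19.5 - abs(stats::rnorm(nw, sd = 3))
    raster_tile(v, lon0, lat0, dx12, dy12)
  })

  # mangrove extent on its native 25 m grid: 1 where the nearest 12 m pixel
  # is land
  dy25 <- 25 / M_PER_DEG
  dx25 <- 25 / (M_PER_DEG * cos(lat0 * pi / 180))
  n25r <- ceiling(n * dy12 / dy25); n25c <- ceiling(n * dx12 / dx25)
  ext25 <- raster_tile(matrix(0, n25r, n25c), lon0, lat0, dx25, dy25)
  land12 <- raster_tile((!water) * 1, lon0, lat0, dx12, dy12)
  ext25 <- with_values(ext25, resample_nearest(land12, ext25)$values)
  ext25$values[is.na(ext25$values)] <- 0

  # two-country EEZ split at a meridian through the scene
  split_lon <- lon0 + dx12 * n * stats::runif(1, 0.4, 0.6)
  ext_deg <- tile_extent(truth_tile)
  rect <- function(x1, x2, y1, y2)
    cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1))
  eez_polygons <- list(
    list(label = 1L, rings = list(rect(ext_deg["xmin"] - dx12, split_lon,
                                       ext_deg["ymin"] - dy12, ext_deg["ymax"] + dy12))),
    list(label = 2L, rings = list(rect(split_lon, ext_deg["xmax"] + dx12,
                                       ext_deg["ymin"] - dy12, ext_deg["ymax"] + dy12))))
  eez_labels <- rasterize_polygons(eez_polygons, truth_tile)

  scene <- structure(list(
    config = config,
    truth_chm_12m = truth_tile,
    tdx_dem = tdx_tile,
    undulation = und_tile,
    ref_dem_30m = ref_tile,
    backscatter_stack = stack,
    mangrove_extent = ext25,
    eez_polygons = eez_polygons,
    eez_labels = eez_labels,
    water_mask_12m = raster_tile(water * 1, lon0, lat0, dx12, dy12),
    artifact_mask = raster_tile(artifact * 1, lon0, lat0, dx12, dy12)
  ), class = "synthetic_scene")
  scene$als_chm_1m <- generate_als_chm(scene, config$als_noise_sd_m)
  scene$shots <- generate_shots(scene, config)
  scene
}

# quality fields of clean shots drawn well inside the passing ranges
clean_quality_fields <- function(n) {
  tibble::tibble(
    quality_flag = rep(1L, n),
    degrade_flag = rep(0L, n),
    num_modes = sample(1:4, n, replace = TRUE),
    dem_minus_egm = stats::runif(n, 0, 45),
    water_persistence_landsat = stats::runif(n, 0, 70),
    elev_lowestmode_minus_mss = stats::runif(n, -4, 4),
    total_energy = stats::runif(n, 3000, 20000)
  )
}

#' Generate lidar footprints over a scene
#'
#' Each shot samples the footprint-scale mean of the truth field within a
#' 12.5 m radius of its true location, with additive Gaussian vertical noise
#' on RH98 and an isotropic Gaussian jitter on the reported location.
#' Exactly `round(contamination_fraction * n_shots)` shots are given one
#' failing quality field each, drawn uniformly over the filter criteria; the
#' failing criterion is recorded in `contaminated_by` so filter accounting
#' is testable.
#'
#' @param scene a `synthetic_scene` (its truth and water mask are used).
#' @param config a [scene_config()]; seeded independently of
#'   [generate_scene()] so repeated calls reproduce the same table.
#' @return tibble of shots (one row per footprint).
#' @export
generate_shots <- function(scene, config = scene$config) {
  if (config$n_shots <= 0) stop("n_shots must be > 0")
  set.seed(config$seed + 1L)
  truth <- scene$truth_chm_12m
  n <- nrow(truth$values)
  # sample from the tile interior: footprints straddling the tile border
  # would be served by the adjacent tile of a real mosaic
  margin <- 2L
  interior <- matrix(FALSE, n, n)
  interior[(margin + 1):(n - margin), (margin + 1):(n - margin)] <- TRUE
  land_cells <- which(!is.na(truth$values) & interior)
  xs <- x_centers(truth); ys <- y_centers(truth)
  # sample positions until every footprint covers at least 3 valid truth
  # pixels (a 25 m footprint centered near a pixel-edge midpoint of a 12 m
  # grid covers only 2 centers; such under-covered footprints carry too
  # little DEM information to calibrate against and are resampled)
  true_lon <- true_lat <- rh_true <- numeric(config$n_shots)
  for (i in seq_len(config$n_shots)) {
    repeat {
      cell <- sample(land_cells, 1)
      r0 <- (cell - 1L) %% n + 1L
      c0 <- (cell - 1L) %/% n + 1L
      lon_i <- xs[c0] + stats::runif(1, -0.5, 0.5) * truth$dx
      lat_i <- ys[r0] + stats::runif(1, -0.5, 0.5) * truth$dy
      px <- footprint_pixels(lon_i, lat_i, truth)
      v <- truth$values[px]
      v <- v[!is.na(v)]
      if (length(v) >= 3) break
    }
    true_lon[i] <- lon_i
    true_lat[i] <- lat_i
    rh_true[i] <- mean(v)
  }

  jit_deg_lat <- config$geolocation_jitter_sd_m / M_PER_DEG
  jit_deg_lon <- jit_deg_lat / cos(config$origin_lon_lat[2] * pi / 180)
  shots <- tibble::tibble(
    shot_id = sprintf("shot_%06d", seq_len(config$n_shots)),
    lon = true_lon + stats::rnorm(config$n_shots, sd = jit_deg_lon),
    lat = true_lat + stats::rnorm(config$n_shots, sd = jit_deg_lat),
    true_lon = true_lon, true_lat = true_lat,
    rh98 = rh_true + stats::rnorm(config$n_shots, sd = config$rh_noise_sd_m)
  )
  shots <- cbind(shots, clean_quality_fields(config$n_shots))
  shots <- tibble::as_tibble(shots)
  shots$contaminated_by <- NA_character_

  n_bad <- round(config$contamination_fraction * config$n_shots)
  if (n_bad > 0) {
    bad <- sample.int(config$n_shots, n_bad)
    crit <- sample(c("degrade_flag", "quality_flag", "num_modes",
                     "dem_minus_egm", "water_persistence", "lowest_mode_mss",
                     "total_energy", "rh98_range"), n_bad, replace = TRUE)
    for (j in seq_along(bad)) {
      i <- bad[j]
      switch(crit[j],
        degrade_flag = { shots$degrade_flag[i] <- 1L },
        quality_flag = { shots$quality_flag[i] <- 0L },
        num_modes = { shots$num_modes[i] <- sample(c(0L, 5L, 6L, 7L), 1) },
        dem_minus_egm = { shots$dem_minus_egm[i] <- stats::runif(1, 55, 90) },
        water_persistence = {
          shots$water_persistence_landsat[i] <- stats::runif(1, 81, 100) },
        lowest_mode_mss = {
          shots$elev_lowestmode_minus_mss[i] <-
            sample(c(-1, 1), 1) * stats::runif(1, 6, 12) },
        total_energy = {
          shots$total_energy[i] <- if (stats::runif(1) < 0.5)
            stats::runif(1, 100, 1500) else stats::runif(1, 26000, 40000) },
        rh98_range = {
          shots$rh98[i] <- if (stats::runif(1) < 0.5)
            -stats::runif(1, 0.5, 2) else stats::runif(1, 61, 70) })
    }
    shots$contaminated_by[bad] <- crit
  }
  shots
}

#' Generate a 1 m airborne canopy height model of the scene truth
#'
#' A 1 m grid with 12 x 12 pixels per 12 m cell; each 1 m pixel carries the
#' cell's truth height plus independent Gaussian noise. Water (nodata) cells
#' in the truth map to nodata 1 m pixels. With zero noise, aggregating back
#' to 12 m by the mean reproduces the truth exactly.
#'
#' @param scene a `synthetic_scene`.
#' @param noise_sd_m per-pixel Gaussian noise sd (m).
#' @return 1 m [raster_tile()].
#' @export
generate_als_chm <- function(scene, noise_sd_m = scene$config$als_noise_sd_m) {
  set.seed(scene$config$seed + 2L)
  truth <- scene$truth_chm_12m
  f <- 12L
  big <- truth$values[rep(seq_len(nrow(truth$values)), each = f),
                      rep(seq_len(ncol(truth$values)), each = f)]
  if (noise_sd_m > 0) {
    nz <- !is.na(big)
    big[nz] <- big[nz] + stats::rnorm(sum(nz), sd = noise_sd_m)
  }
  raster_tile(big, truth$xmin, truth$ymax, truth$dx / f, truth$dy / f,
              vdatum = "geoid")
}

#' Write a scene to a directory of plain-text artefacts
#'
#' Rasters go to the package's text raster format, shots to CSV and the
#' configuration to YAML.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("truth_chm_12m", "tdx_dem", "undulation", "ref_dem_30m",
               "mangrove_extent", "eez_labels", "water_mask_12m",
               "als_chm_1m"))
    write_raster_txt(scene[[nm]], file.path(dir, paste0(nm, ".txt")))
  for (i in seq_along(scene$backscatter_stack))
    write_raster_txt(scene$backscatter_stack[[i]],
                     file.path(dir, sprintf("backscatter_%02d.txt", i)))
  utils::write.csv(scene$shots, file.path(dir, "shots.csv"), row.names = FALSE)
  cfg <- scene$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
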