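#' Quality-filter configuration for lidar footprints
#'
#' Thresholds of the shot-retention cascade (the L2A quality fields, the
#' footprint zonal statistics of the 12 m DEM, and the binned outlier rule).
#' Retention requires: degrade flag 0; quality flag 1; number of detected
#' modes >= 1 and < 5; (GEDI-reported DEM - EGM2008) < 50 m; Landsat water
#' persistence < 80; |elevation of lowest mode - mean sea surface| < 5 m;
#' total energy > 2000 and < 25000; footprint max DEM > 0 and < 60 m;
#' footprint min DEM < 60 m; RH98 > 0 and < 60 m; at least 3 DEM pixels in
#' the footprint; and footprint DEM standard deviation < 1.5 m (3-4 pixels),
#' < 2 m (5-6 pixels) or < 3 m (> 6 pixels). All comparisons strict except
#' `num_modes >= 1` and `count >= 3`.
#'
#' @param footprint_diameter_m lidar footprint diameter (m).
#' @param min_modes,max_modes_exclusive detected-mode bounds.
#' @param max_dem_minus_egm_m reported-DEM-minus-geoid bound (m).
#' @param max_water_persistence Landsat water-persistence bound (percent).
#' @param max_abs_lowestmode_minus_mss_m lowest-mode-vs-sea-surface bound (m).
#' @param energy_range open interval of acceptable total energy.
#' @param tdx_max_range_m open interval for the footprint max DEM value (m).
#' @param tdx_min_max_m upper bound for the footprint min DEM value (m).
#' @param rh98_range_m open interval for RH98 (m).
#' @param sd_limits_m footprint-sd bounds (m) keyed by pixel count:
#'   `count_3_4`, `count_5_6`, `count_gt6`.
#' @param min_pixel_count minimum DEM pixels under the footprint.
#' @param outlier_bin_width_m bin width of the binned outlier rule (m).
#' @param outlier_sigma deviation threshold in bin standard deviations.
#' @param outlier_min_bin_n bins with fewer members are exempt from the
#'   outlier rule (sigma unstable).
#' @export
filter_config <- function(footprint_diameter_m = 25,
                          min_modes = 1, max_modes_exclusive = 5,
                          max_dem_minus_egm_m = 50,
                          max_water_persistence = 80,
                          max_abs_lowestmode_minus_mss_m = 5,
                          energy_range = c(2000, 25000),
                          tdx_max_range_m = c(0, 60),
                          tdx_min_max_m = 60,
                          rh98_range_m = c(0, 60),
                          sd_limits_m = c(count_3_4 = 1.5, count_5_6 = 2,
                                          count_gt6 = 3),
                          min_pixel_count = 3,
                          outlier_bin_width_m = 2,
                          outlier_sigma = 3,
                          outlier_min_bin_n = 3) {
  structure(as.list(environment()), class = "filter_config")
}

# first-fail evaluation order and reason codes of the cascade
REJECT_REASONS <- c("degrade_flag", "quality_flag", "num_modes",
                    "dem_minus_egm", "water_persistence", "lowest_mode_mss",
                    "total_energy", "tdx_max_range", "tdx_min", "rh98_range",
                    "pixel_count", "tdx_sd",
                    "binned_outlier_dem", "binned_outlier_rh98")

#' DEM pixels under a lidar footprint
#'
#' Linear indices of the DEM pixels whose centers lie within half the
#' footprint diameter (12.5 m for a 25 m footprint) of the shot center;
#' great-circle distance is approximated locally (equirectangular about the
#' shot). A shot outside the grid extent yields an empty set.
#'
#' @param lon,lat shot center (degrees).
#' @param dem [raster_tile()] on the 12 m grid.
#' @param radius_m footprint radius (m).
#' @return integer vector of linear indices into `dem$values`.
#' @export
footprint_pixels <- function(lon, lat, dem, radius_m = 12.5) {
  xs <- x_centers(dem); ys <- y_centers(dem)
  dlat <- radius_m / M_PER_DEG
  dlon <- radius_m / (M_PER_DEG * cos(lat * pi / 180))
  rows <- which(ys >= lat - dlat & ys <= lat + dlat)
  cols <- which(xs >= lon - dlon & xs <= lon + dlon)
  if (!length(rows) || !length(cols)) return(integer(0))
  east <- (xs[cols] - lon) * M_PER_DEG * cos(lat * pi / 180)
  north <- (ys[rows] - lat) * M_PER_DEG
  d2 <- outer(north^2, east^2, `+`)
  hit <- which(d2 <= radius_m^2, arr.ind = TRUE)
  if (!nrow(hit)) return(integer(0))
  sort((cols[hit[, 2]] - 1L) * nrow(dem$values) + rows[hit[, 1]])
}

#' Zonal statistics of DEM pixels under a footprint
#'
#' Mean, min, max, sample (n-1) standard deviation and count over the VALID
#' (non-nodata) pixels only. A single valid pixel has sd 0 by convention;
#' zero valid pixels yield NA statistics and count 0.
#'
#' @param pixels linear indices from [footprint_pixels()].
#' @param dem [raster_tile()].
#' @return list with `mean`, `min`, `max`, `sd`, `count`.
#' @export
footprint_stats <- function(pixels, dem) {
  v <- dem$values[pixels]
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0)
    return(list(mean = NA_real_, min = NA_real_, max = NA_real_,
                sd = NA_real_, count = 0L))
  list(mean = mean(v), min = min(v), max = max(v),
       sd = if (n > 1) stats::sd(v) else 0, count = n)
}

#' Pair shots with footprint zonal statistics
#'
#' Joins each shot's RH98 and quality fields to the zonal statistics of the
#' mangrove-masked DEM under its reported 25 m footprint.
#'
#' @param shots tibble of shots (as produced by [generate_shots()] or read
#'   from CSV with the same schema).
#' @param dem mangrove-only height [raster_tile()].
#' @param cfg a [filter_config()].
#' @return tibble of footprint pairs with columns `tdx_mean`, `tdx_min`,
#'   `tdx_max`, `tdx_sd`, `tdx_count` appended.
#' @export
pair_shots <- function(shots, dem, cfg = filter_config()) {
  r <- cfg$footprint_diameter_m / 2
  stats_list <- lapply(seq_len(nrow(shots)), function(i) {
    footprint_stats(footprint_pixels(shots$lon[i], shots$lat[i], dem, r), dem)
  })
  shots$tdx_mean <- vapply(stats_list, `[[`, 0, "mean")
  shots$tdx_min <- vapply(stats_list, `[[`, 0, "min")
  shots$tdx_max <- vapply(stats_list, `[[`, 0, "max")
  shots$tdx_sd <- vapply(stats_list, `[[`, 0, "sd")
  shots$tdx_count <- vapply(stats_list, function(s) as.integer(s$count), 0L)
  shots
}

#' Quality-filter cascade
#'
#' Applies the retention criteria of [filter_config()] in a fixed order
#' (degrade, quality, modes, reported DEM - geoid, water persistence,
#' lowest mode - sea surface, energy, footprint max, footprint min, RH98
#' range, pixel count, sd by count) and records the FIRST failing criterion
#' per shot. `kept` is TRUE iff every criterion passes.
#'
#' @param pairs tibble from [pair_shots()].
#' @param cfg a [filter_config()].
#' @return `pairs` with `kept` (logical) and `reject_reason` (code or NA).
#' @export
quality_filter <- function(pairs, cfg = filter_config()) {
  need <- c("degrade_flag", "quality_flag", "num_modes", "dem_minus_egm",
            "water_persistence_landsat", "elev_lowestmode_minus_mss",
            "total_energy", "tdx_max", "tdx_min", "rh98", "tdx_sd",
            "tdx_count")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing field(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(pairs))
  fail <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- code
  }
  with(pairs, {
    fail(degrade_flag != 0, "degrade_flag")
    fail(quality_flag != 1, "quality_flag")
    fail(!(num_modes >= cfg$min_modes & num_modes < cfg$max_modes_exclusive),
         "num_modes")
    fail(!(dem_minus_egm < cfg$max_dem_minus_egm_m), "dem_minus_egm")
    fail(!(water_persistence_landsat < cfg$max_water_persistence),
         "water_persistence")
    fail(!(abs(elev_lowestmode_minus_mss) < cfg$max_abs_lowestmode_minus_mss_m),
         "lowest_mode_mss")
    fail(!(total_energy > cfg$energy_range[1] &
             total_energy < cfg$energy_range[2]), "total_energy")
    fail(!(tdx_max > cfg$tdx_max_range_m[1] &
             tdx_max < cfg$tdx_max_range_m[2]), "tdx_max_range")
    fail(!(tdx_min < cfg$tdx_min_max_m), "tdx_min")
    fail(!(rh98 > cfg$rh98_range_m[1] & rh98 < cfg$rh98_range_m[2]),
         "rh98_range")
    fail(tdx_count < cfg$min_pixel_count, "pixel_count")
    sd_lim <- ifelse(tdx_count <= 4, cfg$sd_limits_m[["count_3_4"]],
                     ifelse(tdx_count <= 6, cfg$sd_limits_m[["count_5_6"]],
                            cfg$sd_limits_m[["count_gt6"]]))
    fail(!(tdx_sd < sd_lim), "tdx_sd")
  })
  pairs$kept <- is.na(reason)
  pairs$reject_reason <- reason
  pairs
}

#' Binned 3-sigma outlier removal
#'
#' Two marginal passes over the kept pairs: (a) within each RH98 bin of
#' `outlier_bin_width_m`, pairs whose footprint max DEM deviates more than
#' `outlier_sigma` sample standard deviations from the bin's DEM mean are
#' removed; (b) likewise within each max-DEM bin for RH98. A pair removed by
#' either pass is removed (bin statistics are computed once, on the input).
#' Bins with fewer than `outlier_min_bin_n` members are exempt. Safeguards
#' against land-cover change between the InSAR and lidar acquisitions.
#'
#' @param pairs tibble from [quality_filter()] (rows with `kept = FALSE` are
#'   passed through untouched); a tibble without `kept` is treated as all
#'   kept.
#' @param cfg a [filter_config()].
#' @return `pairs` with `kept`/`reject_reason` updated (codes
#'   `binned_outlier_dem`, `binned_outlier_rh98`).
#' @export
binned_outlier_filter <- function(pairs, cfg = filter_config()) {
  if (!nrow(pairs)) {
    pairs$kept <- logical(0); pairs$reject_reason <- character(0)
    return(pairs)
  }
  if (!"kept" %in% names(pairs)) {
    pairs$kept <- TRUE
    pairs$reject_reason <- NA_character_
  }
  idx <- which(pairs$kept)
  x <- pairs$tdx_max[idx]; y <- pairs$rh98[idx]
  w <- cfg$outlier_bin_width_m
  flag_pass <- function(bin_var, test_var) {
    bin <- floor(bin_var / w)
    out <- logical(length(bin_var))
    for (b in unique(bin)) {
      members <- which(bin == b)
      if (length(members) < cfg$outlier_min_bin_n) next
      m <- mean(test_var[members]); s <- stats::sd(test_var[members])
      out[members] <- abs(test_var[members] - m) > cfg$outlier_sigma * s
    }
    out
  }
  bad_dem <- flag_pass(y, x)   # DEM outliers within RH98 bins
  bad_rh <- flag_pass(x, y)    # RH98 outliers within DEM bins
  pairs$kept[idx[bad_dem]] <- FALSE
  pairs$reject_reason[idx[bad_dem]] <- "binned_outlier_dem"
  rh_only <- bad_rh & !bad_dem
  pairs$kept[idx[rh_only]] <- FALSE
  pairs$reject_reason[idx[rh_only]] <- "binned_outlier_rh98"
  pairs
}

#' Write / read footprint-pair tables
#'
#' CSV mirroring the deposited calibration-shot table: geolocation, quality
#' fields and RH98 alongside the extracted DEM zonal statistics (mean,
#' minimum, maximum, standard deviation, pixel count) plus
#' `kept`/`reject_reason`.
#'
#' @param pairs tibble of pairs.
#' @param path CSV path.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
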