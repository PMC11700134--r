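#' DEM preparation configuration
#'
#' Thresholds for artifact replacement against the coarse reference DEM and
#' for clipping to the plausible mangrove height range.
#'
#' @param artifact_threshold_m where the absolute DEM-vs-reference difference
#'   exceeds this (meters), the reference value replaces the DEM value.
#' @param max_height_m heights above this are treated as invalid (above the
#'   maximum known mangrove height) and set to nodata.
#' @param min_height_m heights below this are treated as bare ground and set
#'   to nodata.
#' @return a `dem_prep_config` list.
#' @export
dem_prep_config <- function(artifact_threshold_m = 30,
                            max_height_m = 60,
                            min_height_m = 0.1) {
  if (artifact_threshold_m <= 0) stop("artifact_threshold_m must be > 0")
  if (!(0 < min_height_m && min_height_m < max_height_m))
    stop("need 0 < min_height_m < max_height_m")
  structure(list(artifact_threshold_m = artifact_threshold_m,
                 max_height_m = max_height_m,
                 min_height_m = min_height_m),
            class = "dem_prep_config")
}

#' Convert ellipsoidal heights to geoid (orthometric) heights
#'
#' Subtracts the geoid undulation N at every pixel: H = h - N. The undulation
#' grid is resampled to the tile grid (nearest neighbor) when permitted.
#'
#' @param tile elevation [raster_tile()] with `vdatum = "ellipsoid"`.
#' @param undulation geoid undulation [raster_tile()] (meters).
#' @param resample allow internal nearest-neighbor resampling of the
#'   undulation grid when it is not co-registered (default TRUE).
#' @return the tile with geoid-referenced heights (`vdatum = "geoid"`).
#' @export
convert_to_geoid <- function(tile, undulation, resample = TRUE) {
  if (is.na(tile$vdatum) || tile$vdatum != "ellipsoid")
    stop("tile must be ellipsoid-referenced")
  if (!same_grid(tile, undulation)) {
    if (!resample) stop("undulation grid is not co-registered with the tile")
    undulation <- resample_nearest(undulation, tile)
  }
  with_values(tile, tile$values - undulation$values, vdatum = "geoid")
}

#' Replace gross DEM artifacts using the reference DEM
#'
#' Pixels where the 12 m DEM and the coarse reference DEM (already resampled
#' to the 12 m grid) disagree by more than the artifact threshold take the
#' reference value; all other pixels are unchanged. Nodata in the DEM stays
#' nodata. Applied per pixel with the absolute difference.
#'
#' @param tdx 12 m DEM [raster_tile()], geoid-referenced.
#' @param ref reference DEM on the same grid, geoid-referenced.
#' @param cfg a [dem_prep_config()].
#' @return the artifact-replaced DEM.
#' @export
replace_artifacts <- function(tdx, ref, cfg = dem_prep_config()) {
  if (!identical(tdx$vdatum, ref$vdatum))
    stop("vertical datum mismatch between DEM and reference")
  if (!same_grid(tdx, ref)) stop("DEM and reference are not co-registered")
  v <- tdx$values
  swap <- !is.na(v) & !is.na(ref$values) &
    abs(v - ref$values) > cfg$artifact_threshold_m
  v[swap] <- ref$values[swap]
  with_values(tdx, v)
}

#' Clip heights to the plausible mangrove range
#'
#' Pixels above `max_height_m` (above the maximum known mangrove height) or
#' below `min_height_m` (bare ground) are set to nodata, not clamped.
#'
#' @param tile geoid-referenced height [raster_tile()].
#' @param cfg a [dem_prep_config()].
#' @export
clip_heights <- function(tile, cfg = dem_prep_config()) {
  v <- tile$values
  v[!is.na(v) & (v > cfg$max_height_m | v < cfg$min_height_m)] <- NA_real_
  with_values(tile, v)
}
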