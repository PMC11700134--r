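#' Run the full canopy-height pipeline on one scene
#'
#' Chains every stage: vertical datum harmonisation, artifact replacement
#' against the coarse reference DEM, backscatter water-persistence masking,
#' extent resampling and mangrove-only subsetting, height clipping, shot
#' pairing with the quality-filter cascade and the binned outlier rule, the
#' category-weighted regression (70/30 stratified split), application of the
#' selected model to the DEM, and hold-out validation.
#'
#' @param scene a `synthetic_scene` from [generate_scene()] (or any list
#'   with the same elements read from disk).
#' @param dem_cfg a [dem_prep_config()].
#' @param water_cfg a [water_mask_config()].
#' @param filter_cfg a [filter_config()].
#' @param calibration `"fit"` to fit and select a model from the scene's
#'   shots, or `"identity"` to apply the identity model (noiseless closure
#'   runs).
#' @param split_frac training fraction of the stratified split.
#' @param seed RNG seed of the split.
#' @return list with the masked DEM (`masked_dem`), the calibrated
#'   `height_map`, `pairs` (full accounting table), `weights`, `split`,
#'   `models`, the selected `model`, and `validation` (NULL for identity
#'   runs).
#' @export
run_pipeline <- function(scene,
                         dem_cfg = dem_prep_config(),
                         water_cfg = water_mask_config(),
                         filter_cfg = filter_config(),
                         calibration = c("fit", "identity"),
                         split_frac = 0.7,
                         seed = 1L) {
  calibration <- match.arg(calibration)

  geoid_dem <- convert_to_geoid(scene$tdx_dem, scene$undulation)
  ref12 <- resample_nearest(scene$ref_dem_30m, geoid_dem)
  dem <- replace_artifacts(geoid_dem, ref12, dem_cfg)

  persistence <- water_persistence(scene$backscatter_stack, water_cfg)
  water <- classify_water(persistence, water_cfg)
  extent12 <- resample_nearest(scene$mangrove_extent, geoid_dem)
  extent12$values[is.na(extent12$values)] <- 0
  masked <- apply_masks(dem, list(mangrove_extent = extent12, water = water))
  masked <- clip_heights(masked, dem_cfg)

  pairs <- pair_shots(scene$shots, masked, filter_cfg)
  pairs <- quality_filter(pairs, filter_cfg)
  pairs <- binned_outlier_filter(pairs, filter_cfg)
  kept <- pairs[pairs$kept, , drop = FALSE]

  weights <- NULL; split <- NULL; models <- NULL; validation <- NULL
  if (calibration == "fit") {
    split <- stratified_split(kept, frac = split_frac, seed = seed)
    weights <- compute_category_weights(split$train$rh98)
    models <- fit_candidates(split$train, weights)
    model <- select_model(models)
    validation <- validation_report(split$valid, model)
  } else {
    model <- identity_model()
  }
  height_map <- apply_calibration(model, masked)

  list(masked_dem = masked, height_map = height_map, water_mask = water,
       pairs = pairs, weights = weights, split = split, models = models,
       model = model, validation = validation)
}

#' RMSE of a height map against the scene truth
#'
#' Root mean squared difference over pixels valid in both rasters; the
#' noiseless-closure figure of merit.
#'
#' @param height_map calibrated [raster_tile()].
#' @param truth truth [raster_tile()] on the same grid.
#' @export
map_rmse <- function(height_map, truth) {
  stopifnot(same_grid(height_map, truth))
  ok <- !is.na(height_map$values) & !is.na(truth$values)
  if (!any(ok)) stop("no jointly valid pixels")
  sqrt(mean((height_map$values[ok] - truth$values[ok])^2))
}
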