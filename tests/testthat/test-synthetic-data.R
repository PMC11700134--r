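test_that("scene generation is deterministic for a fixed config", {
  cfg <- scene_config(tile_size_px = 50, n_shots = 120, seed = 99L)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$tdx_dem$values, s2$tdx_dem$values)
  expect_identical(s1$ref_dem_30m$values, s2$ref_dem_30m$values)
  expect_identical(s1$backscatter_stack[[3]]$values,
                   s2$backscatter_stack[[3]]$values)
  expect_identical(s1$shots, s2$shots)
  expect_identical(s1$als_chm_1m$values, s2$als_chm_1m$values)
  # and a different seed changes the scene
  s3 <- generate_scene(scene_config(tile_size_px = 50, n_shots = 120,
                                    seed = 100L))
  expect_false(identical(s1$tdx_dem$values, s3$tdx_dem$values))
})

test_that("with all noise off, the DEM minus undulation is the truth", {
  sc <- generate_scene(noiseless_config(tile_size_px = 40, n_shots = 50))
  diff <- sc$tdx_dem$values - sc$undulation$values
  expect_equal(diff, sc$truth_chm_12m$values, tolerance = 1e-12)
  expect_true(all(sc$truth_chm_12m$values >= 1 &
                    sc$truth_chm_12m$values <= 50))
})

test_that("artifact patches are disjoint and detectable against the reference", {
  cfg <- noiseless_config(tile_size_px = 80, n_shots = 50, artifact_count = 5,
                          artifact_magnitude_m = 90, seed = 5L)
  sc <- generate_scene(cfg)
  ref12 <- resample_nearest(sc$ref_dem_30m, sc$truth_chm_12m)
  geoid <- convert_to_geoid(sc$tdx_dem, sc$undulation)
  exceed <- abs(geoid$values - ref12$values) > 30
  expect_equal(count_patches(exceed), 5)  # brute-force pixel scan
  expect_true(all(exceed[sc$artifact_mask$values == 1]))
})

test_that("scene invariants hold: water backscatter persistence and grids", {
  sc <- generate_scene(scene_config(tile_size_px = 60, n_shots = 50,
                                    water_fraction = 0.15, seed = 12L))
  water <- sc$water_mask_12m$values == 1
  expect_true(any(water))
  low <- Reduce(`+`, lapply(sc$backscatter_stack,
                            function(l) (l$values <= -19) * 1))
  frac <- low / length(sc$backscatter_stack)
  expect_true(all(frac[water] >= 0.70))
  expect_true(is.na(sc$truth_chm_12m$values[which(water)[1]]))
  # 25 m extent raster sits on its own coarser grid
  expect_gt(sc$mangrove_extent$dx, sc$truth_chm_12m$dx)
  expect_true(all(sc$mangrove_extent$values %in% c(0, 1)))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(scene_config(water_fraction = 1.5), "water_fraction")
  expect_error(scene_config(height_range = c(5, 70)), "height_range")
  expect_error(scene_config(artifact_count = 2, artifact_magnitude_m = 10),
               "artifact_magnitude_m")
  expect_error(scene_config(n_shots = 0), "n_shots")
})

test_that("noiseless shots carry the exact footprint truth mean", {
  sc <- generate_scene(noiseless_config(tile_size_px = 50, n_shots = 80,
                                        seed = 3L))
  truth <- sc$truth_chm_12m
  for (i in seq_len(20)) {
    px <- footprint_pixels(sc$shots$lon[i], sc$shots$lat[i], truth)
    expect_equal(sc$shots$rh98[i], mean(truth$values[px], na.rm = TRUE))
  }
  expect_equal(sc$shots$lon, sc$shots$true_lon)
})

test_that("contamination marks exactly the configured number of shots", {
  sc <- generate_scene(accounting_config())
  expect_equal(sum(!is.na(sc$shots$contaminated_by)), 100)
  expect_true(all(sc$shots$contaminated_by[!is.na(sc$shots$contaminated_by)]
                  %in% c("degrade_flag", "quality_flag", "num_modes",
                         "dem_minus_egm", "water_persistence",
                         "lowest_mode_mss", "total_energy", "rh98_range")))
})

test_that("the 1 m airborne CHM nests in and averages back to the truth", {
  sc <- generate_scene(noiseless_config(tile_size_px = 30, n_shots = 50))
  agg <- aggregate_chm(sc$als_chm_1m, sc$truth_chm_12m)
  expect_equal(agg$values, sc$truth_chm_12m$values)

  wet <- generate_scene(scene_config(tile_size_px = 30, n_shots = 50,
                                     water_fraction = 0.2, seed = 8L))
  water_cell <- which(wet$water_mask_12m$values == 1, arr.ind = TRUE)[1, ]
  block <- wet$als_chm_1m$values[(water_cell[1] - 1) * 12 + 1:12,
                                 (water_cell[2] - 1) * 12 + 1:12]
  expect_true(all(is.na(block)))  # nodata truth -> nodata 1 m pixels
})

test_that("noisy 1 m cell means concentrate around the truth as 3 sigma/12 predicts", {
  sc <- generate_scene(noiseless_config(tile_size_px = 30, n_shots = 50,
                                        seed = 21L))
  als <- generate_als_chm(sc, noise_sd_m = 1)
  agg <- aggregate_chm(als, sc$truth_chm_12m)
  dev <- abs(agg$values - sc$truth_chm_12m$values)
  # per-cell mean of 144 iid N(0,1) pixels: sd 1/12; ~99.7% within 3 sd
  expect_gte(mean(dev <= 3 / 12), 0.98)
})

test_that("scenes write to plain-text artefacts that read back", {
  sc <- generate_scene(scene_config(tile_size_px = 25, n_shots = 30,
                                    seed = 2L))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  back <- read_raster_txt(file.path(dir, "truth_chm_12m.txt"))
  expect_equal(back$values, sc$truth_chm_12m$values, tolerance = 1e-10)
  shots <- utils::read.csv(file.path(dir, "shots.csv"))
  expect_equal(nrow(shots), 30)
  cfg <- yaml::read_yaml(file.path(dir, "scene_config.yaml"))
  expect_equal(cfg$seed, 2)
})
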