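# a pair that passes every criterion, with overridable fields
pair_row <- function(...) {
  row <- tibble::tibble(degrade_flag = 0L, quality_flag = 1L, num_modes = 2L,
                        dem_minus_egm = 10, water_persistence_landsat = 20,
                        elev_lowestmode_minus_mss = 0, total_energy = 5000,
                        tdx_max = 10, tdx_min = 8, rh98 = 10, tdx_sd = 0.5,
                        tdx_count = 5L)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

test_that("footprint pixel selection follows 12.5 m center distance", {
  dem <- tile_m(matrix(0, 9, 9))
  xs <- x_centers(dem); ys <- y_centers(dem)
  # shot exactly on the center pixel's center: that pixel plus the 4-neighbor
  # cross (12 m < 12.5 m), diagonals excluded (17 m)
  px <- footprint_pixels(xs[5], ys[5], dem)
  expect_true(((5 - 1) * 9 + 5) %in% px)
  expect_length(px, 5)
  # shot on a 4-pixel corner junction: the 4 touching pixels (8.5 m), next
  # ring excluded (19 m)
  corner_lon <- (xs[4] + xs[5]) / 2; corner_lat <- (ys[4] + ys[5]) / 2
  expect_length(footprint_pixels(corner_lon, corner_lat, dem), 4)
  # shot outside the extent: empty set
  expect_length(footprint_pixels(xs[9] + 1, ys[1], dem), 0)
})

test_that("footprint pixel selection matches the exhaustive distance oracle", {
  set.seed(41)
  dem <- tile_m(matrix(0, 11, 13), lon0 = 20, lat0 = -8)
  ext <- tile_extent(dem)
  for (i in 1:30) {
    lon <- runif(1, ext["xmin"], ext["xmax"])
    lat <- runif(1, ext["ymin"], ext["ymax"])
    expect_identical(footprint_pixels(lon, lat, dem),
                     oracle_footprint_pixels(lon, lat, dem))
  }
})

test_that("footprint statistics use valid pixels and sample sd", {
  dem <- tile_m(matrix(c(10, 12, 14, NA), 2, 2), vdatum = "geoid")
  s <- footprint_stats(1:4, dem)
  expect_equal(s[c("mean", "min", "max", "sd", "count")],
               list(mean = 12, min = 10, max = 14, sd = 2, count = 3L))
  s1 <- footprint_stats(1L, dem)
  expect_equal(s1$count, 1L)
  expect_equal(s1$sd, 0)  # single pixel: sd 0 by convention
  expect_equal(footprint_stats(4L, dem)$count, 0L)
})

test_that("the quality cascade keeps compliant shots and reports first failures", {
  ok <- quality_filter(pair_row(num_modes = 2L, tdx_count = 4L, tdx_sd = 1.2))
  expect_true(ok$kept)
  expect_true(is.na(ok$reject_reason))

  cases <- list(
    list(pair_row(tdx_count = 2L, tdx_sd = 0.1), "pixel_count"),
    list(pair_row(tdx_count = 7L, tdx_sd = 3.2), "tdx_sd"),
    list(pair_row(tdx_count = 5L, tdx_sd = 2.0), "tdx_sd"),   # strict <
    list(pair_row(rh98 = -0.5), "rh98_range"),
    list(pair_row(rh98 = 60), "rh98_range"),
    list(pair_row(num_modes = 5L), "num_modes"),
    list(pair_row(num_modes = 0L), "num_modes"),
    list(pair_row(dem_minus_egm = 50), "dem_minus_egm"),
    list(pair_row(water_persistence_landsat = 80), "water_persistence"),
    list(pair_row(elev_lowestmode_minus_mss = -5), "lowest_mode_mss"),
    list(pair_row(total_energy = 2000), "total_energy"),
    list(pair_row(tdx_max = 0), "tdx_max_range"),
    list(pair_row(tdx_max = 60), "tdx_max_range"),
    list(pair_row(tdx_min = 60), "tdx_min"),
    list(pair_row(degrade_flag = 1L), "degrade_flag"),
    list(pair_row(quality_flag = 0L), "quality_flag"))
  for (cs in cases) {
    out <- quality_filter(cs[[1]])
    expect_false(out$kept)
    expect_identical(out$reject_reason, cs[[2]])
  }
  # first-fail ordering: degrade is reported before quality and sd
  multi <- quality_filter(pair_row(degrade_flag = 1L, quality_flag = 0L,
                                   tdx_sd = 9))
  expect_identical(multi$reject_reason, "degrade_flag")
  expect_error(quality_filter(pair_row()[, -1]), "degrade_flag")
})

test_that("filtering is monotone and accounts for every shot", {
  set.seed(42)
  scene <- generate_scene(scene_config(tile_size_px = 60, n_shots = 300,
                                       seed = 7L))
  res <- run_pipeline(scene, seed = 3L)
  p <- res$pairs
  expect_equal(sum(p$kept) + sum(!is.na(p$reject_reason)), nrow(p))
  # disabling the sd criterion can only grow the kept set
  loose <- quality_filter(pair_shots(scene$shots, res$masked_dem),
                          filter_config(sd_limits_m = c(count_3_4 = Inf,
                                                        count_5_6 = Inf,
                                                        count_gt6 = Inf)))
  strict <- quality_filter(pair_shots(scene$shots, res$masked_dem))
  expect_true(all(loose$kept[strict$kept]))
})

test_that("binned outlier removal drops only genuine bin outliers", {
  same <- pair_row()[rep(1, 10), ]
  same$kept <- TRUE; same$reject_reason <- NA_character_
  expect_true(all(binned_outlier_filter(same)$kept))  # zero deviation

  # 200 pairs near the 1:1 line plus one grossly discordant pair; the
  # background is dense enough per 2 m bin that a single outlier cannot
  # hide by inflating its own bin's standard deviation
  set.seed(43)
  x <- runif(200, 1, 19)
  pairs <- tibble::tibble(tdx_max = x, rh98 = x + rnorm(200, sd = 0.3),
                          kept = TRUE, reject_reason = NA_character_)
  planted <- tibble::tibble(tdx_max = 45, rh98 = 5, kept = TRUE,
                            reject_reason = NA_character_)
  all_pairs <- rbind(pairs, planted)
  out <- binned_outlier_filter(all_pairs)
  expect_false(out$kept[201])
  expect_true(all(out$kept[1:200]))
  expect_identical(which(!out$kept),
                   oracle_binned_outliers(all_pairs$tdx_max, all_pairs$rh98))

  empty <- binned_outlier_filter(pairs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("binned outlier removal matches the brute-force oracle on random data", {
  set.seed(44)
  for (i in 1:10) {
    n <- 120
    x <- runif(n, 0, 50)
    y <- x + rnorm(n, sd = runif(1, 0.2, 2))
    pairs <- tibble::tibble(tdx_max = x, rh98 = y)
    out <- binned_outlier_filter(pairs)
    expect_identical(which(!out$kept), oracle_binned_outliers(x, y))
  }
})

test_that("both filters are idempotent on their own output", {
  set.seed(45)
  x <- runif(300, 1, 49)
  pairs <- pair_row()[rep(1, 300), ]
  pairs$tdx_max <- x
  pairs$rh98 <- x + rnorm(300, sd = 0.5)
  once <- binned_outlier_filter(quality_filter(pairs))
  twice <- binned_outlier_filter(quality_filter(once))
  expect_identical(twice$kept, once$kept)
  expect_identical(twice$reject_reason, once$reject_reason)
})

test_that("pair tables round-trip through CSV", {
  p <- quality_filter(pair_row())
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(p, path)
  back <- read_pairs_csv(path)
  expect_equal(back$tdx_max, p$tdx_max)
  expect_equal(back$kept, p$kept)
})
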