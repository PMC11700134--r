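#' Hold-out validation report
#'
#' Applies a calibration model to the validation pairs' footprint max DEM
#' values and reports fit metrics plus the residual distribution binned by
#' 1 m of reference (lidar RH98) height. Residual = map height - reference
#' height.
#'
#' @param valid_pairs tibble with `rh98` and `tdx_max` (a hold-out disjoint
#'   from the training set).
#' @param model a `calibration_model`.
#' @return list with `metrics` (see [evaluate_metrics()]) and
#'   `residual_bins` (tibble: `bin_lower_m`, `n`, `mean_residual_m`,
#'   `sd_residual_m`).
#' @export
validation_report <- function(valid_pairs, model) {
  if (!nrow(valid_pairs)) stop("validation set is empty")
  predicted <- predict(model, valid_pairs$tdx_max)
  observed <- valid_pairs$rh98
  metrics <- evaluate_metrics(predicted, observed)
  res <- predicted - observed
  bin <- floor(observed)
  bins <- sort(unique(bin))
  residual_bins <- tibble::tibble(
    bin_lower_m = bins,
    n = vapply(bins, function(b) sum(bin == b), 0L),
    mean_residual_m = vapply(bins, function(b) mean(res[bin == b]), 0),
    sd_residual_m = vapply(bins, function(b) {
      v <- res[bin == b]
      if (length(v) > 1) stats::sd(v) else 0
    }, 0))
  list(metrics = metrics, residual_bins = residual_bins)
}

#' Aggregate a 1 m canopy height model to the 12 m grid
#'
#' Block mean of the valid 1 m pixels inside each coarse cell. The fine grid
#' must nest exactly in the target grid (shared origin, integer pixel-size
#' ratio). Cells with less than `min_coverage` valid 1 m pixels become
#' nodata.
#'
#' @param als_1m fine [raster_tile()].
#' @param target coarse [raster_tile()] defining the output grid.
#' @param min_coverage minimum valid fraction per cell, in \[0, 1\].
#' @export
aggregate_chm <- function(als_1m, target, min_coverage = 0.5) {
  f <- target$dx / als_1m$dx
  fy <- target$dy / als_1m$dy
  if (abs(f - round(f)) > 1e-6 || abs(fy - round(fy)) > 1e-6 ||
      round(f) != round(fy) ||
      abs(als_1m$xmin - target$xmin) > 1e-9 ||
      abs(als_1m$ymax - target$ymax) > 1e-9 ||
      !identical(dim(als_1m$values), dim(target$values) * as.integer(round(f))))
    stop("fine grid does not nest in the target grid")
  f <- as.integer(round(f))
  nr <- nrow(target$values); nc <- ncol(target$values)
  arr <- array(als_1m$values, dim = c(f, nr, f, nc))
  valid <- apply(!is.na(arr), c(2, 4), sum)
  total <- apply(arr, c(2, 4), sum, na.rm = TRUE)
  out <- total / valid
  out[valid / f^2 < min_coverage] <- NA_real_
  raster_tile(out, target$xmin, target$ymax, target$dx, target$dy,
              crs = target$crs, vdatum = als_1m$vdatum, nodata = target$nodata)
}

#' Per-country height statistics
#'
#' For every country code present in the label raster, computes the 99th
#' percentile (linear interpolation) of all its valid height pixels, the
#' median of its 100 tallest pixel values (median of all values when fewer
#' than 100 exist), and a 1 m histogram of its heights. Countries with no
#' valid pixel are omitted.
#'
#' @param height_map canopy height [raster_tile()].
#' @param country integer-label [raster_tile()] co-registered with the map
#'   (0 = no country).
#' @return tibble with `country_code`, `n_pixels`, `p99_m`,
#'   `median_top100_m` and a list-column `histogram` (named counts per 1 m
#'   bin, names = bin lower edges).
#' @export
country_stats <- function(height_map, country) {
  if (!same_grid(height_map, country))
    stop("country labels are not co-registered with the height map")
  codes <- sort(unique(country$values[country$values > 0 &
                                        !is.na(country$values)]))
  rows <- lapply(codes, function(code) {
    v <- height_map$values[!is.na(height_map$values) &
                             !is.na(country$values) & country$values == code]
    if (!length(v)) return(NULL)
    top <- sort(v, decreasing = TRUE)[seq_len(min(100, length(v)))]
    h <- table(factor(floor(v), levels = 0:ceiling(max(v))))
    tibble::tibble(country_code = as.integer(code),
                   n_pixels = length(v),
                   p99_m = unname(stats::quantile(v, 0.99, type = 7)),
                   median_top100_m = stats::median(top),
                   histogram = list(h))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
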