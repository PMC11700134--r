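#' Postprocessing configuration for tall-tile outlier mitigation
#'
#' Misclassification of inland forests and hills inside the mangrove extent
#' produces implausibly tall pixels in some tiles. Tiles containing any
#' pixel above `flag_height_m` are flagged; the population of flagged tiles'
#' 99th-percentile heights is ordered and a 5th-order polynomial is fitted
#' to locate its inflection, which separates tiles whose tall tail is
#' artifact-driven from tiles of genuinely tall canopy. The inflection
#' threshold is always recomputed from the tile population being processed
#' (for the real global dataset it falls at 31.02 m).
#'
#' @param flag_height_m tiles with any pixel above this (m) are flagged.
#' @param percentile percentile used per tile (linear interpolation).
#' @param poly_order order of the polynomial fitted to the ordered
#'   percentiles.
#' @export
postprocess_config <- function(flag_height_m = 50, percentile = 99,
                               poly_order = 5) {
  if (!(percentile > 0 && percentile < 100)) stop("percentile must be in (0,100)")
  if (poly_order < 3) stop("poly_order must be >= 3")
  structure(list(flag_height_m = flag_height_m, percentile = percentile,
                 poly_order = poly_order), class = "postprocess_config")
}

#' Tall-pixel statistics of a tile
#'
#' Returns NULL unless some valid pixel exceeds `flag_height_m`; otherwise
#' the tile's maximum and its `percentile`-th percentile (linear
#' interpolation between order statistics) over all valid pixels.
#'
#' @param tile calibrated height [raster_tile()].
#' @param cfg a [postprocess_config()].
#' @param tile_id identifier carried into the result.
#' @return list with `tile_id`, `max_m`, `p99_m`, or NULL.
#' @export
tile_tall_stats <- function(tile, cfg = postprocess_config(), tile_id = NA) {
  v <- tile$values[!is.na(tile$values)]
  if (!length(v) || max(v) <= cfg$flag_height_m) return(NULL)
  list(tile_id = tile_id, max_m = max(v),
       p99_m = unname(stats::quantile(v, cfg$percentile / 100, type = 7)))
}

#' Locate the inflection of the ordered tile percentiles
#'
#' Sorts the flagged tiles' percentile values ascending, normalizes ranks to
#' \[0, 1\] for numerical conditioning, fits a polynomial of
#' `cfg$poly_order` by least squares and returns the fitted value at the
#' real root of the polynomial's second derivative inside the rank range.
#' When several sign changes exist the LARGEST root is used: on the
#' J-shaped curves these ordered percentiles form (a shallow ramp of
#' artifact-driven tiles turning into the steep rise of genuinely tall
#' ones), the earlier sign changes are least-squares oscillations over the
#' shallow ramp, while the last marks the turn into sustained convexity.
#' Errors, with diagnostics, when too few values are supplied or no
#' inflection lies in range.
#'
#' @param p99_values percentile heights (m) of the flagged tiles.
#' @param cfg a [postprocess_config()].
#' @return threshold height (m).
#' @export
find_inflection_threshold <- function(p99_values, cfg = postprocess_config()) {
  ord <- cfg$poly_order
  n <- length(p99_values)
  if (n < ord + 2)
    stop(sprintf("need at least %d values to fit an order-%d polynomial (got %d)",
                 ord + 2, ord, n))
  y <- sort(p99_values)
  x <- (seq_len(n) - 1) / (n - 1)
  fit <- stats::lm(y ~ stats::poly(x, ord, raw = TRUE))
  cf <- stats::coef(fit)          # c0 + c1 x + ... + c_ord x^ord
  cf[is.na(cf)] <- 0
  # second derivative coefficients: k(k-1) c_k x^(k-2)
  dd <- vapply(2:ord, function(k) k * (k - 1) * cf[k + 1], 0)
  roots <- polyroot(dd)
  real <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
  inrange <- sort(real[real >= -1e-9 & real <= 1 + 1e-9])
  if (!length(inrange))
    stop(sprintf(paste0("no inflection of the fitted order-%d polynomial lies ",
                        "in the rank range (real second-derivative roots: %s)"),
                 ord, paste(signif(real, 4), collapse = ", ")))
  x0 <- inrange[length(inrange)]
  unname(drop(cbind(1, t(x0^(seq_len(ord)))) %*% cf))
}

#' Mitigate a flagged tile
#'
#' If the tile's 99th percentile is below the inflection threshold, its tall
#' tail is taken to be artifact-driven and every pixel above the percentile
#' is capped at the percentile; otherwise (genuinely tall canopy) the tile
#' is unchanged. Never increases any pixel; idempotent.
#'
#' @param tile calibrated height [raster_tile()].
#' @param stats [tile_tall_stats()] of this tile (NULL for unflagged tiles,
#'   returned unchanged).
#' @param threshold_m inflection threshold from
#'   [find_inflection_threshold()].
#' @export
mitigate_tile <- function(tile, stats, threshold_m) {
  if (is.null(stats) || stats$p99_m >= threshold_m) return(tile)
  v <- tile$values
  v[!is.na(v) & v > stats$p99_m] <- stats$p99_m
  with_values(tile, v)
}
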