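#' Water mask configuration
#'
#' @param backscatter_threshold_db a backscatter value at or below this (dB)
#'   votes "water" in a layer (open water is a low-backscatter surface).
#' @param persistence_threshold fraction of layers, in (0,1): pixels whose
#'   water-vote fraction strictly exceeds it are classified water.
#' @export
water_mask_config <- function(backscatter_threshold_db = -19,
                              persistence_threshold = 0.70) {
  if (!(persistence_threshold > 0 && persistence_threshold < 1))
    stop("persistence_threshold must be in (0,1)")
  structure(list(backscatter_threshold_db = backscatter_threshold_db,
                 persistence_threshold = persistence_threshold),
            class = "water_mask_config")
}

#' Normalized water persistence from a backscatter time stack
#'
#' Each layer is thresholded into a binary water vote (backscatter at or
#' below the threshold), the votes are summed per pixel and normalized by
#' the number of layers in which the pixel is valid, yielding a persistence
#' fraction in \[0, 1\].
#'
#' @param stack nonempty list of co-registered backscatter [raster_tile()]s (dB).
#' @param cfg a [water_mask_config()].
#' @return persistence [raster_tile()] (fraction; NA where no layer is valid).
#' @export
water_persistence <- function(stack, cfg = water_mask_config()) {
  if (length(stack) == 0) stop("backscatter stack is empty")
  base <- stack[[1]]
  votes <- matrix(0, nrow(base$values), ncol(base$values))
  valid <- votes
  for (layer in stack) {
    if (!same_grid(layer, base)) stop("stack layers are not co-registered")
    ok <- !is.na(layer$values)
    valid <- valid + ok
    votes <- votes + (ok & layer$values <= cfg$backscatter_threshold_db)
  }
  frac <- votes / valid
  frac[valid == 0] <- NA_real_
  raster_tile(frac, base$xmin, base$ymax, base$dx, base$dy,
              crs = base$crs, nodata = base$nodata)
}

#' Classify persistent water
#'
#' Water if and only if persistence strictly exceeds the threshold.
#'
#' @param persistence persistence [raster_tile()] from [water_persistence()].
#' @param cfg a [water_mask_config()].
#' @return binary [raster_tile()] (1 water, 0 land, NA where unknown).
#' @export
classify_water <- function(persistence, cfg = water_mask_config()) {
  v <- persistence$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("persistence values must lie in [0, 1]")
  with_values(persistence, (v > cfg$persistence_threshold) * 1)
}

# Even-odd point-in-polygon over a set of rings, boundary-inclusive.
# pts: 2-col matrix of points; rings: list of 2-col vertex matrices
# (closing vertex optional). Boundary points (within tol of an edge) count
# as inside, so pixels centered on a shared border belong to every polygon
# touching it and the caller's tie-break applies.
point_in_rings <- function(pts, rings, tol = 1e-12) {
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(length(px))
  boundary <- logical(length(px))
  for (ring in rings) {
    if (nrow(ring) >= 2 &&
        all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    n <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    j <- n
    for (i in seq_len(n)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
      # distance from point to segment for the boundary-inclusive rule
      vx <- x2 - x1; vy <- y2 - y1
      len2 <- vx * vx + vy * vy
      t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2)) else 0
      d2 <- (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
      boundary <- boundary | d2 <= tol^2
      j <- i
    }
  }
  inside | boundary
}

#' Rasterize labeled polygons onto a grid
#'
#' Assigns to each pixel the label of the polygon containing the pixel
#' center, 0 where none. A pixel center lying on a shared border (or inside
#' several overlapping polygons) takes the lowest label, deterministically.
#'
#' @param polygons list of features, each `list(label = <positive integer>,
#'   rings = <list of 2-column vertex matrices (lon, lat)>)`; a single
#'   matrix may be given in place of a one-ring list.
#' @param target a [raster_tile()] whose grid defines the output.
#' @param boundary_tol distance tolerance for the boundary-inclusive rule,
#'   in CRS units.
#' @return integer-labeled [raster_tile()].
#' @export
rasterize_polygons <- function(polygons, target, boundary_tol = 1e-9) {
  labels <- vapply(polygons, function(p) as.numeric(p$label %||% NA_real_), 0)
  for (k in seq_along(polygons)) {
    p <- polygons[[k]]
    if (is.na(labels[k]) || labels[k] < 1 || labels[k] != round(labels[k]))
      stop(sprintf("feature %d: label must be a positive integer", k))
    rings <- p$rings
    if (is.matrix(rings)) rings <- list(rings)
    if (!length(rings) || any(!vapply(rings, function(r)
      is.matrix(r) && ncol(r) == 2 && nrow(r) >= 3 && all(is.finite(r)), TRUE)))
      stop(sprintf("feature %d (label %d): invalid geometry", k, labels[k]))
    polygons[[k]]$rings <- rings
  }
  xs <- x_centers(target); ys <- y_centers(target)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  out <- matrix(0, nrow(target$values), ncol(target$values))
  # highest label first, so the lowest label is written last and wins ties
  for (k in order(labels, decreasing = TRUE)) {
    hit <- point_in_rings(pts, polygons[[k]]$rings, tol = boundary_tol)
    out[matrix(hit, length(ys), length(xs))] <- labels[k]
  }
  raster_tile(out, target$xmin, target$ymax, target$dx, target$dy,
              crs = target$crs, nodata = target$nodata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read labeled polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features into the
#' feature list accepted by [rasterize_polygons()].
#'
#' @param path GeoJSON file.
#' @param label_field property holding the positive integer label.
#' @export
read_geojson_polygons <- function(path, label_field = "label") {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  lapply(seq_along(feats), function(k) {
    f <- feats[[k]]
    lab <- f$properties[[label_field]]
    if (is.null(lab)) stop(sprintf("feature %d: missing property '%s'", k, label_field))
    geom <- f$geometry
    ring_mat <- function(r) do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(pg) lapply(pg, ring_mat)),
                            recursive = FALSE),
      stop(sprintf("feature %d: unsupported geometry '%s'", k, geom$type)))
    list(label = as.integer(lab), rings = rings)
  })
}

#' Subset a DEM to mangrove-only pixels
#'
#' A pixel is retained iff the mangrove extent is 1 there and the water mask
#' is 0; all other pixels (including NA mask pixels) become nodata.
#'
#' @param dem height [raster_tile()].
#' @param masks list with binary [raster_tile()]s `mangrove_extent` and
#'   `water`, co-registered with the DEM.
#' @export
apply_masks <- function(dem, masks) {
  ext <- masks$mangrove_extent; wat <- masks$water
  if (!same_grid(dem, ext) || !same_grid(dem, wat))
    stop("masks are not co-registered with the DEM")
  keep <- !is.na(ext$values) & ext$values == 1 &
    !is.na(wat$values) & wat$values == 0
  v <- dem$values
  v[!keep] <- NA_real_
  with_values(dem, v)
}
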