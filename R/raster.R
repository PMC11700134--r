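#' Georeferenced raster tile
#'
#' The universal carrier between pipeline stages: a numeric matrix with a
#' north-up affine georeference, a vertical-datum tag for elevation rasters,
#' and nodata semantics. Row 1 is the northernmost row; cell `(r, c)` has its
#' center at `xmin + (c - 0.5) * dx`, `ymax - (r - 0.5) * dy` (pixel-is-area).
#' Invalid pixels are held as `NA` in memory; `nodata` is the sentinel used
#' on disk.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xmin,ymax coordinates of the grid's upper-left corner (CRS units,
#'   degrees for geographic grids).
#' @param dx,dy pixel width and height in CRS units (both positive).
#' @param crs horizontal datum tag (default WGS84 geographic).
#' @param vdatum vertical datum, `"ellipsoid"` or `"geoid"`; `NA` for rasters
#'   that do not carry heights (masks, backscatter, labels).
#' @param nodata sentinel value used when writing to disk.
#' @return an object of class `raster_tile`.
#' @export
raster_tile <- function(values, xmin, ymax, dx, dy = dx,
                        crs = "EPSG:4326", vdatum = NA_character_,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("pixel sizes dx, dy must be positive and finite")
  if (!is.na(vdatum) && !vdatum %in% c("ellipsoid", "geoid"))
    stop("vdatum must be 'ellipsoid', 'geoid' or NA")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, dx = dx, dy = dy,
         crs = crs, vdatum = vdatum, nodata = nodata),
    class = "raster_tile"
  )
}

#' @export
dim.raster_tile <- function(x) dim(x$values)

#' @export
print.raster_tile <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_tile> %d x %d, dx=%g dy=%g, origin (%.6f, %.6f)\n",
              d[1], d[2], x$dx, x$dy, x$xmin, x$ymax))
  cat(sprintf("  crs: %s  vdatum: %s  valid: %d/%d", x$crs, x$vdatum,
              length(v), prod(d)))
  if (length(v)) cat(sprintf("  range: [%.3f, %.3f]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Test for raster_tile
#' @param x object
#' @export
is_raster_tile <- function(x) inherits(x, "raster_tile")

#' Pixel-center coordinates
#'
#' @param tile a [raster_tile()].
#' @return numeric vector of x (easting/longitude) or y (northing/latitude)
#'   coordinates of pixel centers, column-wise / row-wise.
#' @export
x_centers <- function(tile) tile$xmin + (seq_len(ncol(tile$values)) - 0.5) * tile$dx

#' @rdname x_centers
#' @export
y_centers <- function(tile) tile$ymax - (seq_len(nrow(tile$values)) - 0.5) * tile$dy

#' Extent of a tile as (xmin, xmax, ymin, ymax)
#' @param tile a [raster_tile()].
#' @export
tile_extent <- function(tile) {
  d <- dim(tile$values)
  c(xmin = tile$xmin, xmax = tile$xmin + d[2] * tile$dx,
    ymin = tile$ymax - d[1] * tile$dy, ymax = tile$ymax)
}

#' Do two tiles share the same grid?
#' @param a,b raster_tile objects.
#' @param tol relative tolerance on origin/pixel size.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$dx - b$dx) < tol * a$dx && abs(a$dy - b$dy) < tol * a$dy
}

#' Replace the values of a tile, keeping its georeference
#' @param tile a [raster_tile()].
#' @param values replacement matrix of identical dimensions.
#' @param vdatum optionally update the vertical datum tag.
#' @export
with_values <- function(tile, values, vdatum = tile$vdatum) {
  stopifnot(identical(dim(values), dim(tile$values)))
  tile$values <- values
  tile$vdatum <- vdatum
  tile
}

# meters per degree of latitude on the authalic sphere; longitude scales by
# cos(latitude). Good to <0.5% within a 1-degree tile, ample for footprint
# geometry at 12 m pixels.
M_PER_DEG <- pi / 180 * 6371008.8

#' Local meter offsets between points on a geographic grid
#'
#' Equirectangular approximation about `lat0`: east/north offsets in meters
#' of (`lon`, `lat`) relative to (`lon0`, `lat0`).
#'
#' @param lon,lat point coordinates (degrees).
#' @param lon0,lat0 reference point (degrees).
#' @return list with numeric `east_m`, `north_m`.
#' @export
local_meters <- function(lon, lat, lon0, lat0) {
  list(east_m  = (lon - lon0) * M_PER_DEG * cos(lat0 * pi / 180),
       north_m = (lat - lat0) * M_PER_DEG)
}

#' Write / read a raster tile as plain text
#'
#' A self-describing text format: `key value` header lines (dimensions,
#' georeference, vertical datum, nodata) followed by the value matrix, one
#' row per line, north first. `NA` cells are written as the nodata sentinel.
#'
#' @param tile a [raster_tile()].
#' @param path file path.
#' @export
write_raster_txt <- function(tile, path) {
  d <- dim(tile$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("nrows %d", d[1]),
    sprintf("ncols %d", d[2]),
    sprintf("xmin %.12g", tile$xmin),
    sprintf("ymax %.12g", tile$ymax),
    sprintf("dx %.12g", tile$dx),
    sprintf("dy %.12g", tile$dy),
    sprintf("crs %s", tile$crs),
    sprintf("vdatum %s", tile$vdatum),
    sprintf("nodata %.12g", tile$nodata)
  ), con)
  v <- tile$values
  v[is.na(v)] <- tile$nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_txt
#' @export
read_raster_txt <- function(path) {
  hdr <- readLines(path, n = 9)
  kv <- strsplit(hdr, " ", fixed = TRUE)
  key <- vapply(kv, `[`, "", 1)
  val <- vapply(kv, `[`, "", 2)
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 9))
  dimnames(v) <- NULL
  nodata <- as.numeric(val["nodata"])
  v[v == nodata] <- NA_real_
  raster_tile(v,
              xmin = as.numeric(val["xmin"]), ymax = as.numeric(val["ymax"]),
              dx = as.numeric(val["dx"]), dy = as.numeric(val["dy"]),
              crs = unname(val["crs"]),
              vdatum = if (val["vdatum"] == "NA") NA_character_ else unname(val["vdatum"]),
              nodata = nodata)
}

#' Nearest-neighbor resampling onto a target grid
#'
#' Each target pixel takes the value of the source pixel that contains the
#' target pixel's center; target centers falling outside the source extent
#' become nodata. Used to bring the coarser reference DEM and 25 m extent
#' masks onto the common 12 m grid.
#'
#' @param src source [raster_tile()].
#' @param target a [raster_tile()] whose grid defines the output (its values
#'   are ignored).
#' @return a [raster_tile()] on the target grid carrying resampled source
#'   values (and the source's `vdatum`).
#' @export
resample_nearest <- function(src, target) {
  es <- tile_extent(src); et <- tile_extent(target)
  if (es["xmin"] >= et["xmax"] || et["xmin"] >= es["xmax"] ||
      es["ymin"] >= et["ymax"] || et["ymin"] >= es["ymax"])
    stop("source and target extents are disjoint")
  xs <- x_centers(target); ys <- y_centers(target)
  # source cell containing each target center (1-based; outside -> NA)
  cc <- floor((xs - src$xmin) / src$dx) + 1L
  rr <- floor((src$ymax - ys) / src$dy) + 1L
  cc[cc < 1L | cc > ncol(src$values)] <- NA_integer_
  rr[rr < 1L | rr > nrow(src$values)] <- NA_integer_
  out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  ok_r <- which(!is.na(rr)); ok_c <- which(!is.na(cc))
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c] <- src$values[rr[ok_r], cc[ok_c], drop = FALSE]
  raster_tile(out, target$xmin, target$ymax, target$dx, target$dy,
              crs = target$crs, vdatum = src$vdatum, nodata = target$nodata)
}
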