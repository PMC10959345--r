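# Lightweight single-band raster container shared by every pipeline layer.
#
# Grids live in a local equal-area frame: x/y are kilometres from a fixed
# lon/lat anchor, rows run top-down (row 1 = northernmost). Record
# coordinates are geographic (decimal degrees); the anchor plus an
# equirectangular local projection maps between the two. NA is the nodata
# sentinel throughout.

# Kilometres per degree at the equator (longitude is additionally scaled by
# cos(latitude of the anchor)).
KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON <- 111.320

#' Construct a grid raster
#'
#' A `grid_raster` is a numeric matrix plus the georeference needed by the
#' pipeline: cell size (km), the km coordinates of the lower-left corner, a
#' CRS label, and the lon/lat anchor of the local km frame. Rows are stored
#' top-down, so `values[1, 1]` is the north-west cell. `NA` marks nodata.
#'
#' @param values Numeric matrix (rows top-down). `NA` = nodata.
#' @param cell_km Cell side length in kilometres (> 0).
#' @param xmin,ymin Lower-left corner of the grid in the local km frame.
#' @param crs CRS label carried along and compared by [check_shared_grid()].
#' @param origin_lon,origin_lat Geographic anchor of the km frame: the point
#'   `(x = 0, y = 0)` in km corresponds to this lon/lat.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_km = 1, xmin = 0, ymin = 0,
                        crs = "local-km", origin_lon = -73, origin_lat = 4) {
  if (!is.matrix(values) || !is.numeric(values[1]) && !is.logical(values[1])) {
    stop("`values` must be a numeric matrix")
  }
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0) {
    stop("`cell_km` must be a single positive number")
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, cell_km = cell_km, xmin = xmin, ymin = ymin,
         crs = crs, origin_lon = origin_lon, origin_lat = origin_lat),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, %.3g km/cell, crs '%s'\n",
              nrow(v), ncol(v), x$cell_km, x$crs))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Check that rasters share one grid
#'
#' All rasters entering a pipeline stage must agree on shape, cell size,
#' origin and CRS; mismatches abort with the offending raster named.
#'
#' @param ... Named `grid_raster` objects.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_shared_grid <- function(...) {
  rasters <- list(...)
  nm <- names(rasters)
  if (is.null(nm)) nm <- paste0("raster", seq_along(rasters))
  ref <- rasters[[1]]
  for (i in seq_along(rasters)[-1]) {
    r <- rasters[[i]]
    same <- identical(dim(r$values), dim(ref$values)) &&
      isTRUE(all.equal(r$cell_km, ref$cell_km)) &&
      isTRUE(all.equal(r$xmin, ref$xmin)) &&
      isTRUE(all.equal(r$ymin, ref$ymin)) &&
      identical(r$crs, ref$crs)
    if (!same) {
      stop(sprintf("raster '%s' does not share the grid of '%s'",
                   nm[i], nm[1]))
    }
  }
  invisible(TRUE)
}

#' Cell area in square kilometres
#' @param raster A `grid_raster`.
#' @return Scalar cell area (km^2).
#' @export
cell_area_km2 <- function(raster) raster$cell_km^2

# --- coordinate transforms ---------------------------------------------------

#' Convert local km coordinates to lon/lat
#'
#' Equirectangular local projection about the raster anchor; adequate for the
#' landscape extents the pipeline works at (hundreds of km).
#'
#' @param raster A `grid_raster` supplying the anchor.
#' @param x,y Coordinates in the local km frame.
#' @return A list with `lon` and `lat` vectors.
#' @export
km_to_lonlat <- function(raster, x, y) {
  list(
    lon = raster$origin_lon + x / (KM_PER_DEG_LON * cos(raster$origin_lat * pi / 180)),
    lat = raster$origin_lat + y / KM_PER_DEG_LAT
  )
}

#' Convert lon/lat to local km coordinates
#' @inheritParams km_to_lonlat
#' @param lon,lat Geographic coordinates (decimal degrees).
#' @return A list with `x` and `y` vectors (km).
#' @export
lonlat_to_km <- function(raster, lon, lat) {
  list(
    x = (lon - raster$origin_lon) * KM_PER_DEG_LON * cos(raster$origin_lat * pi / 180),
    y = (lat - raster$origin_lat) * KM_PER_DEG_LAT
  )
}

#' Row/column of the cell containing each point
#'
#' Uses the standard raster convention: rows top-down, half-open cell
#' intervals (a point on a cell's left/top edge belongs to that cell).
#' Points outside the grid get `NA` row/col.
#'
#' @param raster A `grid_raster`.
#' @param lon,lat Point coordinates (decimal degrees).
#' @return A data.frame with integer columns `row` and `col`.
#' @export
cell_at <- function(raster, lon, lat) {
  km <- lonlat_to_km(raster, lon, lat)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  ymax <- raster$ymin + nr * raster$cell_km
  col <- floor((km$x - raster$xmin) / raster$cell_km) + 1L
  row <- floor((ymax - km$y) / raster$cell_km) + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Lon/lat of cell centers
#' @param raster A `grid_raster`.
#' @param row,col Cell indices (row 1 = top).
#' @return A list with `lon` and `lat` vectors.
#' @export
cell_center_lonlat <- function(raster, row, col) {
  xy <- cell_center_km(raster, row, col)
  km_to_lonlat(raster, xy$x, xy$y)
}

#' Km coordinates of cell centers
#' @inheritParams cell_center_lonlat
#' @return A list with `x` and `y` vectors (km).
#' @export
cell_center_km <- function(raster, row, col) {
  nr <- nrow(raster$values)
  list(
    x = raster$xmin + (col - 0.5) * raster$cell_km,
    y = raster$ymin + (nr - row + 0.5) * raster$cell_km
  )
}

# --- ESRI ASCII grid I/O -----------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard six-line header; nodata written as
#' -9999. The lon/lat anchor and CRS label go into a small JSON sidecar
#' (`<path>.json`) so round-trips preserve the full georeference.
#'
#' @param raster A `grid_raster`.
#' @param path Output file path (conventionally `.asc`).
#' @return Invisibly `path`.
#' @export
write_ascii_grid <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$xmin),
    sprintf("yllcorner %.10g", raster$ymin),
    sprintf("cellsize %.10g", raster$cell_km),
    "NODATA_value -9999"
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 12),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(
    list(crs = raster$crs, origin_lon = raster$origin_lon,
         origin_lat = raster$origin_lat),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_ascii_grid()] (or any ESRI
#'   ASCII grid; the JSON sidecar is optional).
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  meta <- list(crs = "local-km", origin_lon = -73, origin_lat = 4)
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side)
  grid_raster(m, cell_km = val[["cellsize"]],
              xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              crs = meta$crs, origin_lon = meta$origin_lon,
              origin_lat = meta$origin_lat)
}
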