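# Small in-code fixtures shared across test files.

# A grid_raster from a matrix with 1 km cells at the default anchor.
rast <- function(m, cell_km = 1) jagconn::grid_raster(m, cell_km = cell_km)

# Binary raster with 1s at the given (row, col) cells.
rast_with_ones <- function(nr, nc, cells, cell_km = 1) {
  m <- matrix(0, nr, nc)
  if (length(cells)) m[do.call(rbind, cells)] <- 1
  rast(m, cell_km)
}

# Records data.frame at given lon/lat with uniformly high attributes.
records_at <- function(lon, lat) {
  n <- length(lon)
  data.frame(lon = lon, lat = lat,
             evidence = rep("preserved_specimen", n),
             source = rep("peer_reviewed_article", n),
             department = rep("D01", n), municipality = rep("M001", n),
             stringsAsFactors = FALSE)
}

# Records spaced `gap_km` apart due north from an origin (haversine
# distance along a meridian is exact: gap_km / 6371 radians of latitude).
records_north_line <- function(n, gap_km, lon0 = -73, lat0 = 4) {
  step_deg <- gap_km / 6371 * 180 / pi
  records_at(rep(lon0, n), lat0 + (0:(n - 1)) * step_deg)
}

# Landscape with two rectangular patches on a uniform-resistance field.
# Returns the pieces needed by corridor tests.
two_patch_setup <- function(nr = 20, nc = 40, resistance_value = 1,
                            a_cols = 1:5, b_cols = 36:40, rows = 8:12) {
  mask <- matrix(0, nr, nc)
  mask[rows, a_cols] <- 1
  mask[rows, b_cols] <- 1
  patches <- jagconn::label_patches(rast(mask))
  res <- rast(matrix(resistance_value, nr, nc))
  list(patches = patches, resistance = res)
}

# Random weighted edge list on k nodes (connected not guaranteed).
random_graph_edges <- function(k, p = 0.5) {
  pairs <- utils::combn(k, 2)
  take <- stats::runif(ncol(pairs)) < p
  if (!any(take)) take[sample(ncol(pairs), 1)] <- TRUE
  data.frame(patch_a = pairs[1, take], patch_b = pairs[2, take],
             cwd = stats::runif(sum(take), 0.5, 5))
}
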