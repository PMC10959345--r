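# GeoJSON export of patches (cell-boundary dissolve to polygons) and
# corridors (linestrings through path cell centers). Coordinates are
# written in lon/lat via the raster's local projection.

# Directed boundary edges of one patch, oriented with the interior on the
# left (outer rings counter-clockwise, holes clockwise), chained into
# rings. At pinch vertices (8-connected diagonal touches) the walk prefers
# the sharpest right turn, which splits the boundary into simple rings.
patch_rings <- function(patches, patch_id) {
  lab <- patches$labels
  nr <- nrow(lab); nc <- ncol(lab)
  cells <- patch_cells(patches, patch_id)
  in_patch <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc &&
    lab[r, c] == patch_id
  cell <- patches$cell_km
  xmin <- patches$grid$xmin; ymin <- patches$grid$ymin
  # corner (r, c) = north-west corner of cell (r, c); integer corner grid
  # with x = c - 1, y = nr - r + 1 in cell units.
  edges <- list()
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, "row"]; c <- cells[i, "col"]
    x0 <- c - 1; x1 <- c; yt <- nr - r + 1; yb <- nr - r
    if (!in_patch(r - 1, c)) edges[[length(edges) + 1]] <- c(x1, yt, x0, yt)
    if (!in_patch(r + 1, c)) edges[[length(edges) + 1]] <- c(x0, yb, x1, yb)
    if (!in_patch(r, c - 1)) edges[[length(edges) + 1]] <- c(x0, yt, x0, yb)
    if (!in_patch(r, c + 1)) edges[[length(edges) + 1]] <- c(x1, yb, x1, yt)
  }
  if (!length(edges)) return(list())
  em <- do.call(rbind, edges)
  key <- paste(em[, 1], em[, 2])
  by_start <- split(seq_len(nrow(em)), key)
  used <- rep(FALSE, nrow(em))
  rings <- list()
  turn_pref <- function(din, dout) {
    # prefer the left-most turn: it hugs the current cell, so boundaries
    # that pinch at a corner split into simple rings
    cr <- din[1] * dout[2] - din[2] * dout[1]
    if (cr > 0) 1 else if (cr == 0) 2 else 3
  }
  for (start in seq_len(nrow(em))) {
    if (used[start]) next
    ring <- list(em[start, 1:2])
    e <- start
    repeat {
      used[e] <- TRUE
      ring[[length(ring) + 1]] <- em[e, 3:4]
      cand <- by_start[[paste(em[e, 3], em[e, 4])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1) {
        din <- em[e, 3:4] - em[e, 1:2]
        pref <- vapply(cand, function(j) {
          turn_pref(din, em[j, 3:4] - em[j, 1:2])
        }, numeric(1))
        cand <- cand[which.min(pref)]
      } else cand <- cand[1]
      e <- cand
    }
    ring <- do.call(rbind, ring)
    # to km coordinates
    ring[, 1] <- xmin + ring[, 1] * cell
    ring[, 2] <- ymin + ring[, 2] * cell
    rings[[length(rings) + 1]] <- ring
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Rings -> GeoJSON MultiPolygon coordinates (holes attached to the outer
# ring containing them), converted to lon/lat.
rings_to_multipolygon <- function(raster, rings) {
  areas <- vapply(rings, ring_signed_area, numeric(1))
  outer <- which(areas > 0)
  holes <- which(areas < 0)
  polys <- lapply(outer, function(i) list(rings[[i]]))
  names(polys) <- as.character(outer)
  for (h in holes) {
    pt <- rings[[h]][1, ]
    for (oi in seq_along(outer)) {
      if (point_in_ring(pt[1], pt[2], rings[[outer[oi]]])) {
        polys[[oi]] <- c(polys[[oi]], list(rings[[h]]))
        break
      }
    }
  }
  lapply(polys, function(p) lapply(p, function(ring) {
    ll <- km_to_lonlat(raster, ring[, 1], ring[, 2])
    lapply(seq_along(ll$lon), function(i) c(ll$lon[i], ll$lat[i]))
  }))
}

#' Export patches as GeoJSON polygons
#'
#' Dissolves each patch's cells into polygon rings (with holes) and writes
#' a FeatureCollection with patch attributes; pass `scores` to attach
#' criteria and priority categories.
#'
#' @param patches A `habitat_patches` object.
#' @param path Output `.geojson` path.
#' @param scores Optional `priority_scores` data.frame keyed by `patch_id`.
#' @return Invisibly `path`.
#' @export
write_patches_geojson <- function(patches, path, scores = NULL) {
  feats <- lapply(patches$table$patch_id, function(id) {
    rings <- patch_rings(patches, id)
    props <- as.list(patches$table[patches$table$patch_id == id, ])
    if (!is.null(scores)) {
      row <- scores[scores$patch_id == id, , drop = FALSE]
      if (nrow(row)) {
        props <- c(props, lapply(as.list(row[setdiff(names(row), names(props))]),
                                 function(x) if (is.factor(x)) as.character(x) else x))
      }
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon",
                         coordinates = unname(rings_to_multipolygon(patches$grid,
                                                                    rings))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Export corridors as GeoJSON linestrings
#'
#' One feature per corridor, the line following the least-cost path cell
#' centers, with `patch_a`, `patch_b`, `euclid_km`, `length_km` and `cwd`
#' attributes.
#'
#' @param corridors List of `corridor` objects (e.g. from
#'   `build_network()$corridors`).
#' @param raster Any pipeline `grid_raster` (for the georeference).
#' @param path Output `.geojson` path.
#' @return Invisibly `path`.
#' @export
write_corridors_geojson <- function(corridors, raster, path) {
  feats <- lapply(corridors, function(cr) {
    ll <- cell_center_lonlat(raster, cr$path_cells[, "row"],
                             cr$path_cells[, "col"])
    coords <- lapply(seq_along(ll$lon), function(i) c(ll$lon[i], ll$lat[i]))
    list(type = "Feature",
         properties = list(patch_a = cr$patch_a, patch_b = cr$patch_b,
                           euclid_km = cr$euclid_km,
                           length_km = cr$length_km, cwd = cr$cwd),
         geometry = list(type = "LineString", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
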