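# Remnant habitat patches: habitat-cover selection within the binary
# distribution, connected-component labeling, the minimum-area filter, and
# per-patch / per-region summaries.

#' Habitat class set
#'
#' @param class_ids Land-cover category codes counted as habitat; defaults
#'   to the eight habitat classes of [landcover_classes()].
#' @param class_names Optional labels, matched by position.
#' @return A list of class `habitat_class_set`.
#' @export
habitat_class_set <- function(class_ids = NULL, class_names = NULL) {
  lc <- landcover_classes()
  if (is.null(class_ids)) {
    class_ids <- lc$class_id[lc$habitat]
    class_names <- lc$class_name[lc$habitat]
  }
  if (length(class_ids) == 0) stop("habitat class set must be non-empty")
  if (is.null(class_names)) {
    class_names <- as.character(lc$class_name[match(class_ids, lc$class_id)])
    class_names[is.na(class_names)] <- paste0("class_", class_ids[is.na(class_names)])
  }
  structure(list(class_ids = as.integer(class_ids),
                 class_names = class_names),
            class = "habitat_class_set")
}

#' Habitat mask: habitat covers inside the distribution
#'
#' A cell is habitat iff its land cover belongs to the habitat class set
#' and the binary distribution is 1 there.
#'
#' @param landcover Categorical `grid_raster`.
#' @param classes A [habitat_class_set()].
#' @param distribution Binary `grid_raster` on the same grid.
#' @return A binary `grid_raster`.
#' @export
habitat_mask <- function(landcover, classes, distribution) {
  check_shared_grid(landcover = landcover, distribution = distribution)
  out <- landcover
  out$values <- ifelse(
    is.na(landcover$values) | is.na(distribution$values), NA_real_,
    as.numeric(landcover$values %in% classes$class_ids &
                 distribution$values == 1))
  out
}

#' Label habitat patches
#'
#' Partitions the mask's 1-cells into maximal connected components.
#' Patch ids are assigned in decreasing area order, ties broken by the
#' patch's top-left cell in row-major order.
#'
#' @param mask Binary `grid_raster`.
#' @param connectivity 4 (rook) or 8 (queen, default) neighbourhood.
#' @return An object of class `habitat_patches`: `labels` (integer matrix,
#'   0 = background), `table` (data.frame `patch_id`, `n_cells`,
#'   `area_km2`), `cell_km` and the source `grid` georeference.
#' @export
label_patches <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  m <- mask$values
  im <- matrix(0L, nrow(m), ncol(m))
  im[!is.na(m) & m == 1] <- 1L
  raw <- .cpp_label_components(im, as.integer(connectivity))
  ids <- sort(unique(raw[raw > 0]))
  if (length(ids) == 0) {
    return(structure(list(labels = raw,
                          table = data.frame(patch_id = integer(0),
                                             n_cells = integer(0),
                                             area_km2 = numeric(0)),
                          cell_km = mask$cell_km, grid = mask),
                     class = "habitat_patches"))
  }
  n_cells <- tabulate(raw[raw > 0], nbins = max(ids))[ids]
  # top-left cell in row-major order, for deterministic tie-breaks
  rowmajor <- (row(raw) - 1L) * ncol(raw) + col(raw)
  topleft <- vapply(ids, function(i) min(rowmajor[raw == i]), numeric(1))
  ord <- order(-n_cells, topleft)
  relabel <- integer(max(ids))
  relabel[ids[ord]] <- seq_along(ids)
  labels <- raw
  labels[raw > 0] <- relabel[raw[raw > 0]]
  structure(
    list(labels = labels,
         table = data.frame(patch_id = seq_along(ids),
                            n_cells = n_cells[ord],
                            area_km2 = n_cells[ord] * mask$cell_km^2),
         cell_km = mask$cell_km, grid = mask),
    class = "habitat_patches"
  )
}

#' @export
print.habitat_patches <- function(x, ...) {
  cat(sprintf("<habitat_patches> %d patches, total %.1f km2\n",
              nrow(x$table), sum(x$table$area_km2)))
  invisible(x)
}

#' Drop patches below a minimum area
#'
#' Retains patches whose area is greater than or equal to the threshold;
#' the 23.5 km^2 default keeps patches down to stepping-stone size.
#' Dropped patches are zeroed out of the label matrix; surviving patch ids
#' are unchanged.
#'
#' @param patches A `habitat_patches` object.
#' @param min_area_km2 Minimum area (>= 0).
#' @return The filtered `habitat_patches`.
#' @export
filter_min_area <- function(patches, min_area_km2 = 23.5) {
  if (!is.numeric(min_area_km2) || min_area_km2 < 0) {
    stop("`min_area_km2` must be >= 0")
  }
  keep <- patches$table$area_km2 >= min_area_km2
  dropped <- patches$table$patch_id[!keep]
  patches$labels[patches$labels %in% dropped] <- 0L
  patches$table <- patches$table[keep, , drop = FALSE]
  rownames(patches$table) <- NULL
  patches
}

#' Cells of one patch
#' @param patches A `habitat_patches` object.
#' @param patch_id Patch id.
#' @return Integer matrix with columns `row`, `col`.
#' @export
patch_cells <- function(patches, patch_id) {
  idx <- which(patches$labels == patch_id, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

# Boundary cells of a patch: patch cells with at least one non-patch
# 8-neighbour or on the grid edge.
patch_boundary_cells <- function(patches, patch_id) {
  lab <- patches$labels
  cells <- patch_cells(patches, patch_id)
  nr <- nrow(lab); nc <- ncol(lab)
  on_edge <- cells[, "row"] == 1L | cells[, "row"] == nr |
    cells[, "col"] == 1L | cells[, "col"] == nc
  interior <- !on_edge
  if (any(interior)) {
    r <- cells[interior, "row"]; c <- cells[interior, "col"]
    all_nbrs <- rep(TRUE, length(r))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      all_nbrs <- all_nbrs & lab[cbind(r + dr, c + dc)] == patch_id
    }
    boundary <- on_edge
    boundary[interior] <- !all_nbrs
  } else {
    boundary <- on_edge
  }
  cells[boundary, , drop = FALSE]
}

#' Summarize patches by size class, land cover and region
#'
#' @param patches A `habitat_patches` object.
#' @param landcover Optional categorical `grid_raster` for dominant covers.
#' @param region Optional categorical `grid_raster` of region labels.
#' @param size_breaks Size-class bin edges in km^2.
#' @return A list: `per_patch` data.frame (area, dominant cover, region),
#'   `size_hist` counts per size class, `region_totals` per-region area and
#'   percent share, `mean_area`, `sd_area`, `total_area_km2`,
#'   `largest_patch_km2` and `largest_patch_pct`.
#' @export
patch_summaries <- function(patches, landcover = NULL, region = NULL,
                            size_breaks = c(23.5, 100, 1200, 5000, Inf)) {
  tab <- patches$table
  per <- tab
  per$dominant_cover <- rep(NA_character_, nrow(tab))
  per$region <- rep(NA_integer_, nrow(tab))
  lc_names <- landcover_classes()
  for (i in seq_len(nrow(tab))) {
    cells <- patch_cells(patches, tab$patch_id[i])
    if (!is.null(landcover)) {
      cv <- landcover$values[cells]
      dom <- as.integer(names(sort(table(cv), decreasing = TRUE))[1])
      nm <- lc_names$class_name[match(dom, lc_names$class_id)]
      per$dominant_cover[i] <- if (is.na(nm)) as.character(dom) else nm
    }
    if (!is.null(region)) {
      rv <- region$values[cells]
      per$region[i] <- as.integer(names(sort(table(rv), decreasing = TRUE))[1])
    }
  }
  size_hist <- if (nrow(tab)) {
    table(cut(tab$area_km2, breaks = c(0, size_breaks),
              right = FALSE, include.lowest = TRUE))
  } else table(factor(levels = "none"))
  region_totals <- NULL
  if (!is.null(region) && nrow(tab)) {
    agg <- stats::aggregate(area_km2 ~ region, data = per, FUN = sum)
    agg$percent <- 100 * agg$area_km2 / sum(tab$area_km2)
    region_totals <- agg
  }
  total <- sum(tab$area_km2)
  list(
    per_patch = per,
    size_hist = size_hist,
    region_totals = region_totals,
    mean_area = if (nrow(tab)) mean(tab$area_km2) else 0,
    sd_area = if (nrow(tab) > 1) stats::sd(tab$area_km2) else 0,
    total_area_km2 = total,
    largest_patch_km2 = if (nrow(tab)) max(tab$area_km2) else 0,
    largest_patch_pct = if (total > 0) 100 * max(tab$area_km2) / total else 0
  )
}
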