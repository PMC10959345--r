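# Post-processing of a continuous habitat-suitability surface into the
# binary potential distribution: correlated-predictor pruning, binarization
# at the minimum training presence, elevation refinement, and protection
# accounting.

#' Prune highly correlated predictors
#'
#' Greedy elimination on Spearman rank correlation: while any retained pair
#' has |rho| at or above `threshold`, drop from the worst pair the column
#' with the larger mean absolute correlation to all other retained columns
#' (lexicographic tie-break). Constant columns cannot be ranked against
#' anything; their correlations are treated as 0, with a warning.
#'
#' @param predictors Data.frame or matrix of numeric predictor columns
#'   sampled at shared locations (>= 2 columns).
#' @param threshold Absolute Spearman correlation at or above which a pair
#'   is considered redundant; in (0, 1].
#' @return Character vector of retained column names.
#' @export
prune_correlated <- function(predictors, threshold = 0.8) {
  m <- as.matrix(predictors)
  if (ncol(m) < 2) stop("need at least two predictor columns")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  const <- apply(m, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  if (any(const)) {
    warning("constant column(s) treated as uncorrelated: ",
            paste(colnames(m)[const], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[is.na(rho)] <- 0
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 0
  keep <- colnames(m)
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    if (length(keep) < 2 || max(sub) < threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- rowMeans(sub[pair, , drop = FALSE])
    drop <- if (mean_abs[1] > mean_abs[2]) pair[1]
            else if (mean_abs[2] > mean_abs[1]) pair[2]
            else sort(pair)[2]  # lexicographic: keep the smaller name
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Minimum training presence threshold
#'
#' The lowest suitability value at any presence location; binarizing at this
#' threshold gives zero omission on the training presences. Presences
#' falling on nodata cells (or outside the raster) are skipped with a
#' warning.
#'
#' @param suitability A `grid_raster` of continuous suitability.
#' @param presences Data.frame with `lon` and `lat`.
#' @return The scalar threshold.
#' @export
mtp_threshold <- function(suitability, presences) {
  rc <- cell_at(suitability, presences$lon, presences$lat)
  vals <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc$row)
  vals[ok] <- suitability$values[cbind(rc$row[ok], rc$col[ok])]
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " presence(s) on nodata cells skipped")
  }
  if (all(is.na(vals))) stop("no presence falls on a valid suitability cell")
  min(vals, na.rm = TRUE)
}

#' Binarize a suitability surface
#'
#' @param suitability A `grid_raster`.
#' @param threshold Cells at or above it become 1, below 0; nodata
#'   propagates.
#' @return A binary `grid_raster`.
#' @export
binarize <- function(suitability, threshold) {
  out <- suitability
  out$values <- ifelse(is.na(suitability$values), NA_real_,
                       as.numeric(suitability$values >= threshold))
  out
}

#' Refine a binary distribution by elevation
#'
#' Zeroes cells whose elevation lies outside `[lo, hi]`; the default band
#' is the elevational range with reported jaguar presence (0-3200 m).
#'
#' @param binary Binary `grid_raster`.
#' @param elevation Elevation `grid_raster` (m) on the same grid.
#' @param lo,hi Inclusive elevation band in metres.
#' @return The refined binary `grid_raster`.
#' @export
elevation_refine <- function(binary, elevation, lo = 0, hi = 3200) {
  check_shared_grid(binary = binary, elevation = elevation)
  out <- binary
  outside <- !is.na(elevation$values) &
    (elevation$values < lo | elevation$values > hi)
  out$values[outside & !is.na(out$values)] <- 0
  out
}

#' Protected share of a binary distribution
#'
#' @param binary Binary distribution `grid_raster`.
#' @param protected Binary protected-area `grid_raster` on the same grid.
#' @return A list with `area_km2` (protected distribution area) and
#'   `percent` (share of the distribution protected; 0 with a warning when
#'   the distribution is empty).
#' @export
protected_coverage <- function(binary, protected) {
  check_shared_grid(binary = binary, protected = protected)
  ca <- cell_area_km2(binary)
  dist_cells <- sum(binary$values == 1, na.rm = TRUE)
  both <- sum(binary$values == 1 & protected$values == 1, na.rm = TRUE)
  if (dist_cells == 0) {
    warning("empty distribution: protected percent undefined, returning 0")
    return(list(area_km2 = 0, percent = 0))
  }
  list(area_km2 = both * ca, percent = 100 * both / dist_cells)
}

#' Area of a binary raster in km^2
#' @param binary Binary `grid_raster`.
#' @return Scalar area.
#' @export
binary_area_km2 <- function(binary) {
  sum(binary$values == 1, na.rm = TRUE) * cell_area_km2(binary)
}
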