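# Seeded synthetic landscapes: suitability, elevation, land cover, human
# footprint, protected areas and regions on one shared grid, plus occurrence
# records sampled from the suitability surface. These stand in for national
# geodata so the full pipeline runs and is testable offline.

#' Land-cover codes treated as jaguar habitat
#'
#' Eight natural / semi-natural cover classes considered habitat for the
#' species (dense, open, gallery and fragmented forest, secondary
#' vegetation, natural grasslands, swamps and coastal swamps), plus the
#' non-habitat classes the generator emits.
#'
#' @return A data.frame with `class_id`, `class_name` and logical `habitat`.
#' @export
landcover_classes <- function() {
  data.frame(
    class_id = c(1:8, 9L, 10L),
    class_name = c("dense_forest", "open_forest", "gallery_forest",
                   "fragmented_forest", "secondary_vegetation",
                   "natural_grasslands", "swamps", "coastal_swamps",
                   "pastures_crops", "urban_bare"),
    habitat = c(rep(TRUE, 8), FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic landscape
#'
#' Bundles and validates every knob of the generator. Defaults mirror the
#' study system the pipeline was built for: a ~100 x 100 km window with
#' 1 km cells, 535 raw occurrence records, a bit over half the land in
#' habitat covers, and about a third of cells in near-natural (human
#' footprint < 15) refugia.
#'
#' @param grid_rows,grid_cols Grid dimensions (each >= 10).
#' @param cell_size_km Cell side in km (> 0).
#' @param seed Integer seed; same spec + seed gives bit-identical output.
#' @param n_records Number of occurrence records to draw (>= 1).
#' @param habitat_fraction Target share of cells in habitat land covers.
#' @param n_protected_areas Number of circular protected areas (>= 0).
#' @param hfi_refugia_fraction Target share of cells with HFI < 15.
#' @param smoothness Correlation length of the random fields, in cells.
#' @param duplicate_rate Fraction of records that are exact duplicates of
#'   earlier ones (emulating multi-source compilations).
#' @return A validated list of class `landscape_spec`.
#' @export
landscape_spec <- function(grid_rows = 100, grid_cols = 100, cell_size_km = 1,
                           seed = 1, n_records = 535, habitat_fraction = 0.57,
                           n_protected_areas = 8, hfi_refugia_fraction = 0.32,
                           smoothness = 8, duplicate_rate = 0.1) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid landscape_spec: `%s` %s", field, msg))
  }
  chk(is.numeric(grid_rows) && grid_rows >= 10, "grid_rows", "must be >= 10")
  chk(is.numeric(grid_cols) && grid_cols >= 10, "grid_cols", "must be >= 10")
  chk(is.numeric(cell_size_km) && cell_size_km > 0, "cell_size_km", "must be > 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  chk(is.numeric(n_records) && n_records >= 1, "n_records", "must be >= 1")
  chk(is.numeric(habitat_fraction) && habitat_fraction >= 0 &&
        habitat_fraction <= 1, "habitat_fraction", "must be in [0, 1]")
  chk(is.numeric(n_protected_areas) && n_protected_areas >= 0,
      "n_protected_areas", "must be >= 0")
  chk(is.numeric(hfi_refugia_fraction) && hfi_refugia_fraction >= 0 &&
        hfi_refugia_fraction <= 1, "hfi_refugia_fraction", "must be in [0, 1]")
  chk(is.numeric(smoothness) && smoothness > 0, "smoothness", "must be > 0")
  chk(is.numeric(duplicate_rate) && duplicate_rate >= 0 && duplicate_rate < 1,
      "duplicate_rate", "must be in [0, 1)")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size_km = cell_size_km, seed = as.integer(seed),
         n_records = as.integer(n_records), habitat_fraction = habitat_fraction,
         n_protected_areas = as.integer(n_protected_areas),
         hfi_refugia_fraction = hfi_refugia_fraction, smoothness = smoothness,
         duplicate_rate = duplicate_rate),
    class = "landscape_spec"
  )
}

# Spatially autocorrelated field: Gaussian-smoothed white noise, rescaled to
# [0, 1]. Smoothing is a separable convolution with row-normalized Gaussian
# band matrices, which handles edges without padding artefacts.
smooth_field <- function(rows, cols, sigma) {
  noise <- matrix(stats::rnorm(rows * cols), rows, cols)
  k <- function(n) {
    idx <- seq_len(n)
    m <- exp(-outer(idx, idx, function(i, j) (i - j)^2) / (2 * sigma^2))
    m / rowSums(m)
  }
  sm <- k(rows) %*% noise %*% t(k(cols))
  rng <- range(sm)
  if (rng[1] == rng[2]) return(matrix(0.5, rows, cols))
  (sm - rng[1]) / (rng[2] - rng[1])
}

# Monotone remap of a [0,1] field so that a `frac` share of cells lies below
# `cut` on the target scale [lo, hi]. Rank-preserving, so smooth fields stay
# smooth and the sub-`cut` set stays contiguous.
remap_with_fraction <- function(field, frac, cut, lo, hi) {
  p <- rank(field, ties.method = "first") / length(field)
  out <- field
  if (frac <= 0) {
    out[] <- cut + (hi - cut) * p
  } else if (frac >= 1) {
    out[] <- lo + (cut - lo) * 0.999 * p
  } else {
    below <- p <= frac
    out[below] <- lo + (cut - lo) * (p[below] / frac) * 0.999
    out[!below] <- cut + (hi - cut) * (p[!below] - frac) / (1 - frac)
  }
  matrix(out, nrow(field), ncol(field))
}

#' Generate a synthetic landscape
#'
#' Produces the six co-registered rasters the pipeline consumes:
#' continuous habitat suitability in \[0, 1\], elevation in \[0, 5800\] m
#' (correlated with suitability so high ground is less suitable), a
#' categorical land cover containing the eight habitat classes plus two
#' non-habitat classes, a human footprint index in \[0, 100\] with
#' contiguous low-footprint refugia, a binary protected-area mask built
#' from rasterized circles, and a small Voronoi partition of region labels.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `landscape` with `grid_raster` elements
#'   `suitability`, `elevation`, `landcover`, `hfi`, `protected`, `region`,
#'   and the `spec` itself.
#' @export
generate_landscape <- function(spec) {
  if (!inherits(spec, "landscape_spec")) spec <- do.call(landscape_spec, spec)
  nr <- spec$grid_rows; nc <- spec$grid_cols
  mk <- function(m) grid_raster(m, cell_km = spec$cell_size_km)

  set.seed(spec$seed)

  suit <- smooth_field(nr, nc, spec$smoothness)

  # Elevation shares structure with suitability (high ground less suitable)
  # plus its own relief component; range mimics strong orographic variation.
  relief <- smooth_field(nr, nc, spec$smoothness * 1.5)
  elev_raw <- 0.6 * (1 - suit) + 0.4 * relief
  elev_rng <- range(elev_raw)
  elevation <- 5800 * (elev_raw - elev_rng[1]) / diff(elev_rng)

  # Land cover: threshold an independent smooth field at the habitat
  # fraction, then split each side into classes by quantile.
  lc_field <- smooth_field(nr, nc, spec$smoothness)
  p <- rank(lc_field, ties.method = "first") / length(lc_field)
  landcover <- matrix(0L, nr, nc)
  hab <- p <= spec$habitat_fraction
  if (any(hab)) {
    q <- p[hab] / spec$habitat_fraction
    landcover[hab] <- pmin(8L, 1L + as.integer(floor(q * 8)))
  }
  if (any(!hab)) {
    q <- (p[!hab] - spec$habitat_fraction) / (1 - spec$habitat_fraction)
    landcover[!hab] <- ifelse(q <= 0.7, 9L, 10L)
  }

  # Human footprint: low where suitability is high, remapped so the target
  # share of cells sits under the near-natural cutoff of 15.
  hfi_field <- 0.7 * (1 - suit) + 0.3 * smooth_field(nr, nc, spec$smoothness)
  hfi_rng <- range(hfi_field)
  hfi_field <- (hfi_field - hfi_rng[1]) / diff(hfi_rng)
  hfi <- remap_with_fraction(hfi_field, spec$hfi_refugia_fraction, 15, 0, 100)

  # Protected areas: seeded circles biased towards low-footprint cells.
  protected <- matrix(0, nr, nc)
  if (spec$n_protected_areas > 0) {
    ord <- order(hfi)
    pool <- ord[seq_len(max(1L, floor(length(ord) * 0.5)))]
    centers <- sample(pool, spec$n_protected_areas, replace = TRUE)
    radii <- stats::runif(spec$n_protected_areas, 0.04, 0.12) * min(nr, nc)
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (i in seq_len(spec$n_protected_areas)) {
      cr <- ((centers[i] - 1) %% nr) + 1
      cc <- ((centers[i] - 1) %/% nr) + 1
      protected[(rows - cr)^2 + (cols - cc)^2 <= radii[i]^2] <- 1
    }
  }

  # Regions: Voronoi partition around five seeded sites.
  n_regions <- 5L
  site_r <- stats::runif(n_regions, 1, nr)
  site_c <- stats::runif(n_regions, 1, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d_min <- matrix(Inf, nr, nc); region <- matrix(1L, nr, nc)
  for (k in seq_len(n_regions)) {
    d <- (rows - site_r[k])^2 + (cols - site_c[k])^2
    take <- d < d_min
    region[take] <- k; d_min[take] <- d[take]
  }

  structure(
    list(suitability = mk(suit), elevation = mk(elevation),
         landcover = mk(landcover), hfi = mk(hfi), protected = mk(protected),
         region = mk(region), spec = spec),
    class = "landscape"
  )
}

#' Sample occurrence records from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability; each point
#' is jittered uniformly within its cell so coordinates collide only through
#' the deliberately injected duplicates. Every record carries the evidence,
#' source and administrative-precision attributes that the reliability
#' filter uses, drawn from all of their categories so downstream filtering
#' removes a realistic nonzero fraction.
#'
#' @param suitability A `grid_raster` of suitability values (>= 0).
#' @param n Number of records (>= 1), including duplicates.
#' @param seed Integer seed.
#' @param duplicate_rate Fraction of the n records that replicate an earlier
#'   row exactly (coordinates and attributes).
#' @return A data.frame with columns `lon`, `lat`, `evidence`, `source`,
#'   `department`, `municipality`.
#' @export
generate_records <- function(suitability, n, seed = 1, duplicate_rate = 0.1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a single count >= 1")
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))
  v <- suitability$values
  w <- as.numeric(v); w[is.na(w) | w < 0] <- 0
  if (sum(w) <= 0) stop("suitability has no positive cells to sample from")

  n_dup <- round(n * duplicate_rate)
  n_base <- n - n_dup
  cells <- sample.int(length(w), n_base, replace = TRUE, prob = w)
  nr <- nrow(v)
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  # jitter within the cell (half-open: keep strictly inside)
  ctr <- cell_center_km(suitability, row, col)
  half <- suitability$cell_km / 2
  x <- ctr$x + stats::runif(n_base, -half * 0.98, half * 0.98)
  y <- ctr$y + stats::runif(n_base, -half * 0.98, half * 0.98)
  ll <- km_to_lonlat(suitability, x, y)

  evid <- sample(c("preserved_specimen", "machine_observation",
                   "human_observation", "material_sample", "no_data"),
                 n_base, replace = TRUE,
                 prob = c(0.20, 0.25, 0.30, 0.15, 0.10))
  src <- sample(c("peer_reviewed_article", "expert_validated", "museum",
                  "dataset"), n_base, replace = TRUE,
                prob = c(0.30, 0.30, 0.20, 0.20))
  prec <- sample(c("both", "dept", "muni", "none"), n_base, replace = TRUE,
                 prob = c(0.60, 0.20, 0.10, 0.10))
  dept_pool <- sprintf("D%02d", 1:8)
  muni_pool <- sprintf("M%03d", 1:40)
  department <- ifelse(prec %in% c("both", "dept"),
                       sample(dept_pool, n_base, replace = TRUE), NA)
  municipality <- ifelse(prec %in% c("both", "muni"),
                         sample(muni_pool, n_base, replace = TRUE), NA)

  rec <- data.frame(lon = ll$lon, lat = ll$lat, evidence = evid, source = src,
                    department = department, municipality = municipality,
                    stringsAsFactors = FALSE)
  if (n_dup > 0) {
    rec <- rbind(rec, rec[sample.int(n_base, n_dup, replace = TRUE), ])
    rownames(rec) <- NULL
  }
  rec
}

#' Write landscape rasters and records to a directory
#'
#' One ESRI ASCII grid per raster plus `records.csv`.
#'
#' @param landscape A `landscape` from [generate_landscape()].
#' @param records Optional records data.frame.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly the vector of written paths.
#' @export
write_landscape <- function(landscape, records = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layers <- c("suitability", "elevation", "landcover", "hfi", "protected",
              "region")
  paths <- character(0)
  for (ly in layers) {
    p <- file.path(out_dir, paste0(ly, ".asc"))
    write_ascii_grid(landscape[[ly]], p)
    paths <- c(paths, p)
  }
  if (!is.null(records)) {
    p <- file.path(out_dir, "records.csv")
    utils::write.csv(records, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
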