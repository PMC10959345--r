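# End-to-end orchestration: validated configuration, the staged run
# (records QC -> distribution -> patches -> connectivity ->
# prioritization), artifact output and the run report.

#' Pipeline configuration
#'
#' Validates and freezes every stage parameter. Unknown arguments are
#' rejected. Inputs come either from a [landscape_spec()] (synthetic run)
#' or from a directory of ESRI ASCII grids plus a records CSV as written
#' by [write_landscape()].
#'
#' @param spec A [landscape_spec()] for synthetic input, or `NULL`.
#' @param input_dir Directory with `suitability.asc`, `elevation.asc`,
#'   `landcover.asc`, `hfi.asc`, `protected.asc`, `region.asc` and
#'   `records.csv`; ignored when `spec` is given.
#' @param min_dist_km Spatial thinning distance (km).
#' @param spearman_threshold Correlation cutoff for predictor pruning
#'   (recorded for provenance; pruning is a pre-modeling helper).
#' @param elev_range Elevation band kept in the distribution (m).
#' @param min_area_km2 Minimum patch area.
#' @param max_euclid_km Corridor candidate distance cap.
#' @param hfi_natural_cutoff HFI value under which a cell is near-natural.
#' @param area_breaks Area-score break points (km^2).
#' @param class_breaks Priority-category boundaries.
#' @param connectivity Patch connectivity rule (4 or 8).
#' @param prune_corridors Prune corridors through third patches.
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, input_dir = NULL,
                            min_dist_km = 1, spearman_threshold = 0.8,
                            elev_range = c(0, 3200), min_area_km2 = 23.5,
                            max_euclid_km = 113, hfi_natural_cutoff = 15,
                            area_breaks = c(1200, 5000),
                            class_breaks = c(2, 3, 4),
                            connectivity = 8, prune_corridors = TRUE,
                            seed = 42, out_dir = NULL) {
  if (is.null(spec) && is.null(input_dir)) {
    stop("one of `spec` or `input_dir` is required")
  }
  if (!is.null(spec) && !inherits(spec, "landscape_spec")) {
    stop("`spec` must be a landscape_spec")
  }
  stopifnot(min_dist_km > 0, spearman_threshold > 0, spearman_threshold <= 1,
            length(elev_range) == 2, elev_range[1] <= elev_range[2],
            min_area_km2 >= 0, max_euclid_km > 0,
            length(area_breaks) == 2, length(class_breaks) == 3,
            connectivity %in% c(4, 8))
  structure(
    list(spec = spec, input_dir = input_dir, min_dist_km = min_dist_km,
         spearman_threshold = spearman_threshold, elev_range = elev_range,
         min_area_km2 = min_area_km2, max_euclid_km = max_euclid_km,
         hfi_natural_cutoff = hfi_natural_cutoff, area_breaks = area_breaks,
         class_breaks = class_breaks, connectivity = connectivity,
         prune_corridors = prune_corridors, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

load_inputs <- function(config) {
  if (!is.null(config$spec)) {
    ls <- generate_landscape(config$spec)
    rec <- generate_records(ls$suitability, n = config$spec$n_records,
                            seed = config$spec$seed + 1L,
                            duplicate_rate = config$spec$duplicate_rate)
    list(landscape = ls, records = rec)
  } else {
    layers <- c("suitability", "elevation", "landcover", "hfi", "protected",
                "region")
    ls <- lapply(layers, function(ly) {
      p <- file.path(config$input_dir, paste0(ly, ".asc"))
      if (!file.exists(p)) stop("missing input raster: ", p)
      read_ascii_grid(p)
    })
    names(ls) <- layers
    rec_path <- file.path(config$input_dir, "records.csv")
    if (!file.exists(rec_path)) stop("missing input records: ", rec_path)
    list(landscape = structure(ls, class = "landscape"),
         records = utils::read.csv(rec_path, stringsAsFactors = FALSE))
  }
}

#' Run the full prioritization pipeline
#'
#' Executes record QC, distribution post-processing, patch extraction,
#' corridor/network construction and prioritization in order, optionally
#' writing all artifacts (rasters, tables, GeoJSON, report JSON) to
#' `config$out_dir`. Deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @param landscape,records Optional pre-built inputs overriding the
#'   config's `spec`/`input_dir` (used for engineered test landscapes).
#' @return A list of class `run_report`; see [run_report_json()] for the
#'   serialized schema.
#' @export
run_pipeline <- function(config, landscape = NULL, records = NULL) {
  stage <- "inputs"
  tryCatch({
    if (is.null(landscape)) {
      inp <- load_inputs(config)
      landscape <- inp$landscape
      if (is.null(records)) records <- inp$records
    }
    with(landscape, check_shared_grid(
      suitability = suitability, elevation = elevation, landcover = landcover,
      hfi = hfi, protected = protected, region = region))

    stage <- "records_qc"
    qc <- qc_records(records, min_dist_km = config$min_dist_km,
                     seed = config$seed)

    stage <- "distribution"
    mtp <- mtp_threshold(landscape$suitability, qc$records)
    distribution <- binarize(landscape$suitability, mtp)
    distribution <- elevation_refine(distribution, landscape$elevation,
                                     lo = config$elev_range[1],
                                     hi = config$elev_range[2])
    prot_cov <- protected_coverage(distribution, landscape$protected)
    dist_area <- binary_area_km2(distribution)
    total_area <- sum(!is.na(landscape$suitability$values)) *
      cell_area_km2(landscape$suitability)

    stage <- "patches"
    mask <- habitat_mask(landscape$landcover, habitat_class_set(),
                         distribution)
    patches <- label_patches(mask, connectivity = config$connectivity)
    patches <- filter_min_area(patches, config$min_area_km2)
    summaries <- patch_summaries(patches, landscape$landcover,
                                 landscape$region)

    stage <- "connectivity"
    resistance <- build_resistance(landscape$hfi)
    network <- build_network(patches, resistance,
                             max_euclid_km = config$max_euclid_km,
                             prune = config$prune_corridors)
    corr_stats <- corridor_summaries(network)

    stage <- "prioritization"
    criteria <- compute_criteria(patches, landscape$hfi,
                                 landscape$protected, network$centrality,
                                 hfi_natural_cutoff = config$hfi_natural_cutoff)
    scores <- prioritize(criteria, area_breaks = config$area_breaks,
                         class_breaks = config$class_breaks)
    counts <- priority_counts(scores)

    stage <- "report"
    report <- structure(list(
      seed = config$seed,
      parameters = config[setdiff(names(config), c("spec", "out_dir"))],
      records = as.list(qc$report),
      distribution = list(
        mtp_threshold = mtp,
        area_km2 = dist_area,
        study_area_km2 = total_area,
        pct_of_study_area = area_accounting(dist_area, total_area),
        protected_area_km2 = prot_cov$area_km2,
        protected_pct = area_accounting(prot_cov$area_km2, dist_area)
      ),
      patches = list(
        n_patches = nrow(patches$table),
        total_area_km2 = summaries$total_area_km2,
        pct_of_distribution = area_accounting(summaries$total_area_km2,
                                              dist_area),
        mean_area = summaries$mean_area, sd_area = summaries$sd_area,
        largest_patch_km2 = summaries$largest_patch_km2,
        largest_patch_pct = summaries$largest_patch_pct,
        size_hist = as.list(summaries$size_hist),
        region_totals = summaries$region_totals
      ),
      connectivity = corr_stats[setdiff(names(corr_stats),
                                        "corridor_counts")],
      prioritization = as.list(counts)
    ), class = "run_report")

    if (!is.null(config$out_dir)) {
      stage <- "artifacts"
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ascii_grid(distribution,
                       file.path(config$out_dir, "distribution.asc"))
      utils::write.csv(qc$records,
                       file.path(config$out_dir, "records_qc.csv"),
                       row.names = FALSE)
      utils::write.csv(scores, file.path(config$out_dir, "scores.csv"),
                       row.names = FALSE)
      write_patches_geojson(patches,
                            file.path(config$out_dir, "patches.geojson"),
                            scores = scores)
      write_corridors_geojson(network$corridors, landscape$suitability,
                              file.path(config$out_dir, "corridors.geojson"))
      run_report_json(report, file.path(config$out_dir, "report.json"))
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Percentage accounting with printed-precision rounding
#'
#' `100 * numerator / denominator`, rounded half-up at `digits` decimals
#' (the rounding used when echoing report percentages). A zero denominator
#' yields `NULL`.
#'
#' @param numerator,denominator Scalars.
#' @param digits Decimals to keep (half-up).
#' @return Rounded percentage, or `NULL` when undefined.
#' @export
area_accounting <- function(numerator, denominator, digits = 2) {
  if (is.null(denominator) || denominator == 0) return(NULL)
  pct <- 100 * numerator / denominator
  # round half-up at `digits`
  f <- 10^digits
  sign(pct) * floor(abs(pct) * f + 0.5) / f
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
run_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  records: %d -> %d (filter) -> %d (thin)\n",
              x$records$n_input, x$records$n_after_filter,
              x$records$n_after_thin))
  cat(sprintf("  distribution: %.1f km2 (%.2f%% of study area), %.2f%% protected\n",
              x$distribution$area_km2, x$distribution$pct_of_study_area,
              x$distribution$protected_pct))
  cat(sprintf("  patches: %d covering %.1f km2 (%.2f%% of distribution)\n",
              x$patches$n_patches, x$patches$total_area_km2,
              x$patches$pct_of_distribution))
  cat(sprintf("  corridors: %d; %d/%d patches connected (%.1f%%)\n",
              x$connectivity$n_corridors, x$connectivity$n_connected,
              x$connectivity$n_patches,
              x$connectivity$pct_connected))
  cat(sprintf("  priority areas: %d JPCA (%d I, %d II), %d JPRA (%d I, %d II)\n",
              x$prioritization$JPCA, x$prioritization$JPCA_I,
              x$prioritization$JPCA_II, x$prioritization$JPRA,
              x$prioritization$JPRA_I, x$prioritization$JPRA_II))
  invisible(x)
}
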