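# Occurrence-record quality control: reliability classification from
# evidence / source / geographic precision, removal of low-reliability and
# duplicated records, and spatial thinning to a minimum inter-point
# distance.

RELIABILITY_LEVELS <- c("low", "medium", "high")

#' Default reliability scoring table
#'
#' Maps each record attribute to a reliability level. Evidence:
#' preserved specimens and machine observations (camera traps) rank high,
#' human observations and material samples medium, records with no stated
#' evidence low. Source: peer-reviewed articles and expert-validated
#' records rank high, museums medium; aggregated datasets are of mixed
#' provenance and default to medium (`dataset_level` makes this
#' configurable). Geographic precision: department plus municipality is
#' high, department alone medium, municipality alone or nothing low.
#'
#' @param dataset_level Level for the `dataset` source category
#'   (`"medium"` by default, `"high"` allowed).
#' @return A list of class `reliability_table` with `evidence_level`,
#'   `source_level` and `precision_level` maps.
#' @export
reliability_table <- function(dataset_level = c("medium", "high")) {
  dataset_level <- match.arg(dataset_level)
  structure(
    list(
      evidence_level = c(preserved_specimen = "high",
                         machine_observation = "high",
                         human_observation = "medium",
                         material_sample = "medium",
                         no_data = "low"),
      source_level = c(peer_reviewed_article = "high",
                       expert_validated = "high",
                       museum = "medium",
                       dataset = dataset_level),
      # names encode (has_department, has_municipality)
      precision_level = c("TRUE.TRUE" = "high", "TRUE.FALSE" = "medium",
                          "FALSE.TRUE" = "low", "FALSE.FALSE" = "low")
    ),
    class = "reliability_table"
  )
}

level_num <- function(x) {
  i <- match(x, RELIABILITY_LEVELS)
  if (anyNA(i)) stop("unknown reliability level: ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' Classify record reliability
#'
#' Each record gets a credibility level, the weaker of its evidence and
#' source levels, and an overall reliability, the weaker of credibility and
#' geographic precision (ordering low < medium < high). Taking the minimum
#' at both stages is the conservative reading: a record is only as reliable
#' as its weakest attribute.
#'
#' @param records Data.frame with columns `evidence`, `source`, and either
#'   logical `has_department`/`has_municipality` or character
#'   `department`/`municipality` (non-`NA` meaning present).
#' @param table A [reliability_table()].
#' @return `records` with a `reliability` factor column
#'   (`low`/`medium`/`high`) appended.
#' @export
classify_reliability <- function(records, table = reliability_table()) {
  for (f in c("evidence", "source")) {
    if (!f %in% names(records)) stop(sprintf("records lack a `%s` column", f))
  }
  if (!all(records$evidence %in% names(table$evidence_level))) {
    bad <- setdiff(unique(records$evidence), names(table$evidence_level))
    stop("unknown `evidence` value(s): ", paste(bad, collapse = ", "))
  }
  if (!all(records$source %in% names(table$source_level))) {
    bad <- setdiff(unique(records$source), names(table$source_level))
    stop("unknown `source` value(s): ", paste(bad, collapse = ", "))
  }
  has_dept <- if ("has_department" %in% names(records)) {
    as.logical(records$has_department)
  } else if ("department" %in% names(records)) {
    !is.na(records$department) & records$department != ""
  } else stop("records lack a `department`/`has_department` column")
  has_muni <- if ("has_municipality" %in% names(records)) {
    as.logical(records$has_municipality)
  } else if ("municipality" %in% names(records)) {
    !is.na(records$municipality) & records$municipality != ""
  } else stop("records lack a `municipality`/`has_municipality` column")

  ev <- level_num(unname(table$evidence_level[records$evidence]))
  so <- level_num(unname(table$source_level[records$source]))
  pr <- level_num(unname(table$precision_level[paste(has_dept, has_muni,
                                                     sep = ".")]))
  credibility <- pmin(ev, so)
  overall <- pmin(credibility, pr)
  records$reliability <- factor(RELIABILITY_LEVELS[overall],
                                levels = RELIABILITY_LEVELS)
  records
}

#' Drop low-reliability and duplicated records
#'
#' Removes every record classified `low` and every exact coordinate
#' duplicate (string-normalized lon/lat equality at full input precision;
#' the first occurrence survives). Input order is preserved among
#' survivors.
#'
#' @param records Data.frame with `lon`, `lat` and a `reliability` column
#'   assigned by [classify_reliability()].
#' @param drop_low Drop `low` records (default `TRUE`).
#' @return The filtered data.frame.
#' @export
filter_records <- function(records, drop_low = TRUE) {
  if (!"reliability" %in% names(records)) {
    stop("records are unclassified: run classify_reliability() first")
  }
  keep <- rep(TRUE, nrow(records))
  if (drop_low) keep <- records$reliability != "low"
  key <- paste(format(records$lon, digits = 17, trim = TRUE),
               format(records$lat, digits = 17, trim = TRUE), sep = "|")
  keep <- keep & !duplicated(key)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @param radius_km Earth radius; 6371 km by convention.
#' @return Distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Spatially thin records to a minimum inter-point distance
#'
#' Randomized-greedy thinning: while any pair of retained records lies
#' closer than `min_dist_km` (great-circle), drop the record with the most
#' neighbours inside the radius, breaking ties with the seeded RNG. The
#' result is maximal — no removed record could be re-added without
#' violating the distance constraint — and reproducible for a fixed seed.
#'
#' @param records Deduplicated data.frame with `lon` and `lat`.
#' @param min_dist_km Minimum pairwise distance in km (> 0); 1 km default.
#' @param seed Integer seed for tie-breaking.
#' @return The thinned data.frame, original order preserved.
#' @export
spatial_thin <- function(records, min_dist_km = 1, seed = 1) {
  if (!is.numeric(min_dist_km) || min_dist_km <= 0) {
    stop("`min_dist_km` must be > 0")
  }
  n <- nrow(records)
  if (n <= 1) return(records)
  set.seed(as.integer(seed))
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(records$lon[i], records$lat[i],
                 records$lon[j], records$lat[j])
  })
  close <- d < min_dist_km
  diag(close) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    nbr <- rowSums(close[, alive, drop = FALSE]) * alive
    if (max(nbr) == 0) break
    worst <- which(nbr == max(nbr))
    drop <- if (length(worst) > 1) sample(worst, 1) else worst
    alive[drop] <- FALSE
  }
  out <- records[alive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full record QC stage
#'
#' Classify reliability, drop low/duplicate records, then spatially thin,
#' returning the survivors and a per-stage count report.
#'
#' @inheritParams classify_reliability
#' @inheritParams spatial_thin
#' @param drop_low Drop low-reliability records.
#' @return A list with `records` (the survivors) and `report` (named counts
#'   at each stage).
#' @export
qc_records <- function(records, table = reliability_table(),
                       min_dist_km = 1, seed = 1, drop_low = TRUE) {
  classified <- classify_reliability(records, table)
  filtered <- filter_records(classified, drop_low = drop_low)
  thinned <- spatial_thin(filtered, min_dist_km = min_dist_km, seed = seed)
  list(
    records = thinned,
    report = c(n_input = nrow(records),
               n_low = sum(classified$reliability == "low"),
               n_after_filter = nrow(filtered),
               n_after_thin = nrow(thinned))
  )
}
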