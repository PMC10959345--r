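# Multi-criteria prioritization: per-patch criteria (near-natural share,
# area, protection, centrality), min-max normalization, ordinal area
# scoring, and classification into conservation (JPCA I/II) and recovery
# (JPRA I/II) categories.

PRIORITY_CATEGORIES <- c("JPCA_I", "JPCA_II", "JPRA_I", "JPRA_II")

#' Per-patch prioritization criteria
#'
#' For every patch: the percentage of cells with HFI strictly under the
#' near-natural cutoff (15 by default), the patch area, the percentage of
#' the patch inside protected areas, and its network centrality (0 for
#' isolated patches).
#'
#' @param patches A `habitat_patches` object.
#' @param hfi HFI `grid_raster` on the same grid.
#' @param protected Binary protected-area `grid_raster`.
#' @param centrality Named centrality vector (names = patch ids), e.g.
#'   from [network_centrality()].
#' @param hfi_natural_cutoff HFI value below which a cell counts as
#'   near-natural (strict inequality).
#' @return Data.frame: `patch_id`, `hfi_natural_pct`, `area_km2`,
#'   `protected_pct`, `centrality`.
#' @export
compute_criteria <- function(patches, hfi, protected, centrality,
                             hfi_natural_cutoff = 15) {
  check_shared_grid(patches_grid = patches$grid, hfi = hfi,
                    protected = protected)
  tab <- patches$table
  if (!nrow(tab)) {
    return(data.frame(patch_id = integer(0), hfi_natural_pct = numeric(0),
                      area_km2 = numeric(0), protected_pct = numeric(0),
                      centrality = numeric(0)))
  }
  out <- data.frame(patch_id = tab$patch_id, hfi_natural_pct = NA_real_,
                    area_km2 = tab$area_km2, protected_pct = NA_real_,
                    centrality = NA_real_)
  for (i in seq_len(nrow(tab))) {
    cells <- patch_cells(patches, tab$patch_id[i])
    if (!nrow(cells)) stop("patch ", tab$patch_id[i], " has no cells")
    hv <- hfi$values[cells]
    pv <- protected$values[cells]
    out$hfi_natural_pct[i] <- 100 * sum(hv < hfi_natural_cutoff, na.rm = TRUE) /
      nrow(cells)
    out$protected_pct[i] <- 100 * sum(pv == 1, na.rm = TRUE) / nrow(cells)
    ci <- centrality[as.character(tab$patch_id[i])]
    out$centrality[i] <- if (is.null(ci) || is.na(ci)) 0 else ci
  }
  out
}

#' Min-max normalize the continuous criteria
#'
#' Rescales near-natural percentage, protection percentage and centrality
#' to \[0, 1\] across the patch set. A degenerate (constant) criterion
#' normalizes to 0 for every patch.
#'
#' @param criteria Data.frame from [compute_criteria()].
#' @return The input with `n_hfi`, `n_prot`, `n_cent` columns appended.
#' @export
normalize_criteria <- function(criteria) {
  if (!nrow(criteria)) {
    criteria$n_hfi <- criteria$n_prot <- criteria$n_cent <- numeric(0)
    return(criteria)
  }
  mm <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  criteria$n_hfi <- mm(criteria$hfi_natural_pct)
  criteria$n_prot <- mm(criteria$protected_pct)
  criteria$n_cent <- mm(criteria$centrality)
  criteria
}

#' Ordinal area score
#'
#' Patch size enters the total as an ordinal weight rather than a
#' normalized value: 1 for areas in \[23.5, 1200) km^2 (up to one of the
#' largest reported male home ranges), 2 for \[1200, 5000), and 3 for at
#' least 5000 km^2 (large enough for a population of ~50). Boundaries are
#' assigned to the higher score.
#'
#' @param area_km2 Patch area(s), each >= 23.5.
#' @param breaks Two ascending break points (default 1200 and 5000).
#' @return Integer score(s) in 1:3.
#' @export
area_score <- function(area_km2, breaks = c(1200, 5000)) {
  if (any(area_km2 < 23.5)) {
    stop("area below the 23.5 km^2 patch minimum: should have been filtered")
  }
  ifelse(area_km2 >= breaks[2], 3L, ifelse(area_km2 >= breaks[1], 2L, 1L))
}

#' Classify a total priority score
#'
#' Totals live in \[1, 6\] (three normalized criteria plus the 1-3 area
#' score). Conservation areas: totals above 4 are JPCA I, totals in
#' (3, 4\] are JPCA II. Recovery areas: totals in (2, 3\] are JPRA I,
#' totals of 2 or less are JPRA II.
#'
#' @param total Numeric total score(s).
#' @param class_breaks The three ascending category boundaries
#'   (default 2, 3, 4).
#' @return Factor with levels `JPCA_I`, `JPCA_II`, `JPRA_I`, `JPRA_II`.
#' @export
classify_priority <- function(total, class_breaks = c(2, 3, 4)) {
  out <- ifelse(total > class_breaks[3], "JPCA_I",
         ifelse(total > class_breaks[2], "JPCA_II",
         ifelse(total > class_breaks[1], "JPRA_I", "JPRA_II")))
  factor(out, levels = PRIORITY_CATEGORIES)
}

#' Score and classify every patch
#'
#' Normalizes the criteria, applies the ordinal area score, sums to the
#' total (`n_hfi + n_prot + n_cent + area_score`, range \[1, 6\]) and
#' assigns the JPCA/JPRA category.
#'
#' @param criteria Data.frame from [compute_criteria()].
#' @param area_breaks Break points for [area_score()].
#' @param class_breaks Category boundaries for [classify_priority()].
#' @return Data.frame of class `priority_scores`: criteria columns plus
#'   `n_hfi`, `n_prot`, `n_cent`, `area_score`, `total`, `category`.
#' @export
prioritize <- function(criteria, area_breaks = c(1200, 5000),
                       class_breaks = c(2, 3, 4)) {
  sc <- normalize_criteria(criteria)
  if (!nrow(sc)) {
    sc$area_score <- integer(0); sc$total <- numeric(0)
    sc$category <- factor(character(0), levels = PRIORITY_CATEGORIES)
    class(sc) <- c("priority_scores", class(sc))
    return(sc)
  }
  sc$area_score <- area_score(sc$area_km2, breaks = area_breaks)
  sc$total <- sc$n_hfi + sc$n_prot + sc$n_cent + sc$area_score
  sc$category <- classify_priority(sc$total, class_breaks = class_breaks)
  class(sc) <- c("priority_scores", class(sc))
  sc
}

#' Category counts of a prioritization
#' @param scores A `priority_scores` data.frame.
#' @return Named integer vector over the four categories plus `JPCA` and
#'   `JPRA` totals.
#' @export
priority_counts <- function(scores) {
  tab <- table(scores$category)
  c(as.vector(tab[PRIORITY_CATEGORIES]),
    JPCA = sum(tab[c("JPCA_I", "JPCA_II")]),
    JPRA = sum(tab[c("JPRA_I", "JPRA_II")])) |>
    stats::setNames(c(PRIORITY_CATEGORIES, "JPCA", "JPRA"))
}
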