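# Functional connectivity: human-footprint resistance surface,
# distance-capped least-cost corridors between patches, the patch network,
# and current-flow betweenness centrality.

#' Build a resistance surface from the human footprint index
#'
#' Linear, order-preserving rescale of HFI onto \[1, 100\]:
#' `res = 1 + 99 * (hfi - min) / (max - min)`. A constant HFI degenerates to
#' resistance 1 everywhere. Nodata stays nodata (impassable).
#'
#' @param hfi `grid_raster` of human footprint values.
#' @return A `grid_raster` with values in \[1, 100\].
#' @export
build_resistance <- function(hfi) {
  v <- hfi$values
  if (all(is.na(v))) stop("HFI raster has no valid cells")
  rng <- range(v, na.rm = TRUE)
  out <- hfi
  out$values <- if (rng[1] == rng[2]) {
    ifelse(is.na(v), NA_real_, 1)
  } else {
    1 + 99 * (v - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Patch pairs within a maximum Euclidean distance
#'
#' Distance is measured edge-to-edge, between the nearest boundary-cell
#' centers of the two patches; pairs at exactly the cap are included. The
#' default cap of 113 km is the species' median dispersal distance.
#'
#' @param patches A `habitat_patches` object with >= 2 patches.
#' @param max_euclid_km Distance cap in km.
#' @return Data.frame with `patch_a`, `patch_b`, `euclid_km`.
#' @export
candidate_pairs <- function(patches, max_euclid_km = 113) {
  ids <- patches$table$patch_id
  out <- data.frame(patch_a = integer(0), patch_b = integer(0),
                    euclid_km = numeric(0))
  if (length(ids) < 2) return(out)
  bnd <- lapply(ids, function(i) patch_boundary_cells(patches, i))
  names(bnd) <- as.character(ids)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      a <- bnd[[i]]; b <- bnd[[j]]
      d <- .cpp_min_pair_dist(a[, "row"], a[, "col"], b[, "row"], b[, "col"],
                              patches$cell_km)
      if (d <= max_euclid_km) {
        out <- rbind(out, data.frame(patch_a = ids[i], patch_b = ids[j],
                                     euclid_km = d))
      }
    }
  }
  out
}

#' Least-cost corridor between two patches
#'
#' Minimum cost-weighted-distance path over the 8-connected grid between
#' any cell of `a` and any cell of `b` (multi-source Dijkstra with every
#' cell of `a` as a zero-cost source). A move costs the mean of the two
#' endpoint resistances times the move length (1 or sqrt(2) cell sides);
#' nodata cells are impassable. Returns `NULL` when no finite-cost path
#' exists.
#'
#' @param resistance Resistance `grid_raster` (values >= 1, NA impassable).
#' @param patches A `habitat_patches` object on the same grid.
#' @param a,b Patch ids (disjoint patches).
#' @return A list of class `corridor`: `patch_a`, `patch_b`, `path_cells`
#'   (matrix row/col from a to b), `euclid_km`, `length_km`, `cwd`; or
#'   `NULL`.
#' @export
least_cost_corridor <- function(resistance, patches, a, b) {
  check_shared_grid(resistance = resistance, patches_grid = patches$grid)
  res <- .cpp_lcp(resistance$values, patches$labels, as.integer(a),
                  as.integer(b), patches$cell_km)
  if (!is.finite(res$cwd)) return(NULL)
  path <- cbind(row = res$path_row, col = res$path_col)
  steps <- diff(path)
  length_km <- sum(sqrt(steps[, 1]^2 + steps[, 2]^2)) * patches$cell_km
  ba <- patch_boundary_cells(patches, a)
  bb <- patch_boundary_cells(patches, b)
  euclid <- .cpp_min_pair_dist(ba[, "row"], ba[, "col"],
                               bb[, "row"], bb[, "col"], patches$cell_km)
  structure(list(patch_a = a, patch_b = b, path_cells = path,
                 euclid_km = euclid, length_km = length_km, cwd = res$cwd),
            class = "corridor")
}

#' Drop corridors that pass through a third patch
#'
#' If the least-cost path between A and B runs through another patch C,
#' the A-B link is redundant: connectivity is represented by the A-C and
#' C-B corridors instead, as in standard linkage mapping.
#'
#' @param corridors List of `corridor` objects.
#' @param patches The `habitat_patches` the corridors were built on.
#' @return The pruned corridor list.
#' @export
prune_through_cores <- function(corridors, patches) {
  keep <- vapply(corridors, function(cr) {
    lab <- patches$labels[cr$path_cells]
    !any(lab != 0 & lab != cr$patch_a & lab != cr$patch_b)
  }, logical(1))
  corridors[keep]
}

#' Assemble the patch connectivity network
#'
#' Computes corridors for every candidate pair (keeping the least-cost
#' corridor per pair), optionally prunes corridors that cross third
#' patches, and stores the result as an undirected network.
#'
#' @param patches A `habitat_patches` object.
#' @param resistance Resistance `grid_raster`.
#' @param max_euclid_km Euclidean distance cap for candidate pairs.
#' @param prune Prune corridors passing through third patches (default on).
#' @return A list of class `connectivity_network`: `nodes` (patch table),
#'   `edges` (data.frame patch_a/patch_b/euclid_km/length_km/cwd),
#'   `corridors` (list with path cells), `centrality` (named vector).
#' @export
build_network <- function(patches, resistance, max_euclid_km = 113,
                          prune = TRUE) {
  pairs <- candidate_pairs(patches, max_euclid_km)
  corridors <- list()
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      cr <- least_cost_corridor(resistance, patches,
                                pairs$patch_a[k], pairs$patch_b[k])
      if (!is.null(cr)) corridors[[length(corridors) + 1L]] <- cr
    }
  }
  if (prune) corridors <- prune_through_cores(corridors, patches)
  edges <- if (length(corridors)) {
    do.call(rbind, lapply(corridors, function(cr) {
      data.frame(patch_a = cr$patch_a, patch_b = cr$patch_b,
                 euclid_km = cr$euclid_km, length_km = cr$length_km,
                 cwd = cr$cwd)
    }))
  } else {
    data.frame(patch_a = integer(0), patch_b = integer(0),
               euclid_km = numeric(0), length_km = numeric(0),
               cwd = numeric(0))
  }
  net <- structure(list(nodes = patches$table, edges = edges,
                        corridors = corridors, centrality = NULL),
                   class = "connectivity_network")
  net$centrality <- network_centrality(net)
  net
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(sprintf("<connectivity_network> %d patches, %d corridors\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Current-flow betweenness centrality of the patch network
#'
#' Circuit-theoretic importance of each patch: edges carry conductance
#' 1/cwd, a unit current is injected at every source-target pair within a
#' connected component, and a node's throughput for a pair is half the sum
#' of the absolute currents on its incident edges (endpoints of the pair
#' excluded). The centrality is the unnormalized sum over all pairs of the
#' component; isolated nodes score 0.
#'
#' @param network A `connectivity_network`.
#' @return Named numeric vector of centralities (names = patch ids).
#' @export
network_centrality <- function(network) {
  ids <- network$nodes$patch_id
  cent <- stats::setNames(numeric(length(ids)), ids)
  edges <- network$edges
  if (!nrow(edges)) return(cent)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$patch_a),
               to = as.character(edges$patch_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids))
  )
  comp <- igraph::components(g)
  cond <- 1 / edges$cwd
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    k <- length(members)
    if (k < 3) next
    idx <- stats::setNames(seq_len(k), members)
    ea <- idx[as.character(edges$patch_a)]
    eb <- idx[as.character(edges$patch_b)]
    in_comp <- !is.na(ea) & !is.na(eb)
    ea <- ea[in_comp]; eb <- eb[in_comp]; w <- cond[in_comp]
    L <- matrix(0, k, k)
    for (e in seq_along(ea)) {
      L[ea[e], eb[e]] <- L[ea[e], eb[e]] - w[e]
      L[eb[e], ea[e]] <- L[eb[e], ea[e]] - w[e]
      L[ea[e], ea[e]] <- L[ea[e], ea[e]] + w[e]
      L[eb[e], eb[e]] <- L[eb[e], eb[e]] + w[e]
    }
    # potentials for unit injection at each node, grounded at node k
    Cmat <- matrix(0, k, k)
    Cmat[-k, -k] <- solve(L[-k, -k])
    tau <- numeric(k)
    for (s in 1:(k - 1)) {
      for (t in (s + 1):k) {
        p <- Cmat[, s] - Cmat[, t]
        cur <- abs(w * (p[ea] - p[eb]))
        th <- numeric(k)
        for (e in seq_along(ea)) {
          th[ea[e]] <- th[ea[e]] + cur[e]
          th[eb[e]] <- th[eb[e]] + cur[e]
        }
        th <- th / 2
        th[c(s, t)] <- 0
        tau <- tau + th
      }
    }
    cent[members] <- tau
  }
  cent
}

#' Corridor and centrality summary statistics
#'
#' @param network A `connectivity_network`.
#' @return A list: `n_patches`, `n_corridors`, per-patch `corridor_counts`,
#'   `n_connected`, `n_isolated`, `pct_connected`, corridor length
#'   mean/sd/min/max, mean corridors per patch, and centrality
#'   mean/sd/max.
#' @export
corridor_summaries <- function(network) {
  ids <- network$nodes$patch_id
  edges <- network$edges
  counts <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(edges)) {
    t1 <- table(c(as.character(edges$patch_a), as.character(edges$patch_b)))
    counts[names(t1)] <- as.numeric(t1)
  }
  n_connected <- sum(counts > 0)
  cent <- network$centrality
  list(
    n_patches = length(ids),
    n_corridors = nrow(edges),
    corridor_counts = counts,
    n_connected = n_connected,
    n_isolated = length(ids) - n_connected,
    pct_connected = if (length(ids)) 100 * n_connected / length(ids) else 0,
    length_mean = if (nrow(edges)) mean(edges$length_km) else 0,
    length_sd = if (nrow(edges) > 1) stats::sd(edges$length_km) else 0,
    length_min = if (nrow(edges)) min(edges$length_km) else 0,
    length_max = if (nrow(edges)) max(edges$length_km) else 0,
    corridors_per_patch_mean = if (length(ids)) mean(counts) else 0,
    corridors_per_patch_sd = if (length(ids) > 1) stats::sd(counts) else 0,
    centrality_mean = if (length(cent)) mean(cent) else 0,
    centrality_sd = if (length(cent) > 1) stats::sd(cent) else 0,
    centrality_max = if (length(cent)) max(cent) else 0
  )
}
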