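# Independent reference implementations used to cross-check the package's
# grid and graph algorithms. Each deliberately takes a different route from
# the code it verifies.

# Least-cost distance between patches a and b via igraph: build the full
# 8-connected grid graph with mean-endpoint-resistance edge weights,
# contract nothing, and take the minimum over all a-cell x b-cell
# shortest-path distances.
oracle_lcp_cwd <- function(resistance, labels, a, b, cell_km) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(resistance[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(resistance[rr, cc])) next
      if (id(rr, cc) <= id(r, c)) next  # undirected: one direction
      len <- if (dr != 0 && dc != 0) sqrt(2) else 1
      from <- c(from, id(r, c)); to <- c(to, id(rr, cc))
      w <- c(w, cell_km * len * (resistance[r, c] + resistance[rr, cc]) / 2)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  acells <- which(labels == a); bcells <- which(labels == b)
  d <- igraph::distances(g, v = acells, to = bcells, weights = w)
  min(d)
}

# Connected-component partition by scan + repeated flood fill in pure R,
# returned as a canonical cell partition (list of sorted cell-index sets,
# ordered by smallest member) so two labelings compare structurally.
oracle_label_partition <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nbrs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
    nbrs <- nbrs[!(nbrs[, 1] == 0 & nbrs[, 2] == 0), ]
  } else {
    nbrs <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  comps <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (!isTRUE(mask[r, c] == 1) || seen[r, c]) next
    stack <- list(c(r, c)); seen[r, c] <- TRUE; cells <- integer(0)
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      cells <- c(cells, (cur[2] - 1L) * nr + cur[1])
      for (k in seq_len(nrow(nbrs))) {
        rr <- cur[1] + nbrs[k, 1]; cc <- cur[2] + nbrs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (isTRUE(mask[rr, cc] == 1) && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
    comps[[length(comps) + 1]] <- as.integer(sort(cells))
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

labels_to_partition <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  comps <- lapply(ids, function(i) sort(which(labels == i)))
  comps[order(vapply(comps, min, numeric(1)))]
}

# Current-flow betweenness by full Laplacian pseudoinverse (MASS::ginv):
# potentials p = G (e_s - e_t), edge currents from the incidence matrix,
# node throughput = half the incident absolute currents, endpoints
# excluded. Dense-matrix route, independent of the reduced-system solve in
# the package.
oracle_current_flow <- function(nodes, edges) {
  k <- length(nodes)
  cent <- setNames(numeric(k), nodes)
  if (!nrow(edges) || k < 3) return(cent)
  idx <- setNames(seq_len(k), nodes)
  m <- nrow(edges)
  B <- matrix(0, m, k)
  w <- 1 / edges$cwd
  for (e in 1:m) {
    B[e, idx[as.character(edges$patch_a[e])]] <- 1
    B[e, idx[as.character(edges$patch_b[e])]] <- -1
  }
  L <- t(B) %*% diag(w, m) %*% B
  G <- MASS::ginv(L)
  # restrict pairs to connected node pairs (same component)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$patch_a),
               to = as.character(edges$patch_b)),
    directed = FALSE, vertices = data.frame(name = nodes))
  memb <- igraph::components(g)$membership[nodes]
  for (s in 1:(k - 1)) for (t in (s + 1):k) {
    if (memb[s] != memb[t]) next
    p <- G[, s] - G[, t]
    cur <- abs(w * (B %*% p))
    th <- numeric(k)
    for (e in 1:m) {
      ia <- which(B[e, ] == 1); ib <- which(B[e, ] == -1)
      th[ia] <- th[ia] + cur[e]; th[ib] <- th[ib] + cur[e]
    }
    th <- th / 2
    th[c(s, t)] <- 0
    cent <- cent + th
  }
  cent
}

# Largest subset of points with all pairwise great-circle distances at or
# above min_dist_km, by exhaustive subset enumeration (n <= 12).
oracle_max_thin_size <- function(lon, lat, min_dist_km) {
  n <- length(lon)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    jagconn::haversine_km(lon[i], lat[i], lon[j], lat[j])
  })
  best <- 0L
  for (code in 0:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    ok <- TRUE
    if (length(members) > 1) {
      pr <- utils::combn(members, 2)
      ok <- all(d[cbind(pr[1, ], pr[2, ])] >= min_dist_km)
    }
    if (ok) best <- length(members)
  }
  best
}
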