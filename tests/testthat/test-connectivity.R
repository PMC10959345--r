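test_that("resistance rescale maps HFI onto [1, 100] order-preservingly", {
  hfi <- rast(matrix(c(0, 25, 50, 100), 2, 2))
  r <- build_resistance(hfi)
  expect_equal(r$values[1, 1], 1)
  expect_equal(r$values[2, 2], 100)
  expect_equal(r$values[1, 2], 50.5)          # midpoint of the HFI range
  expect_equal(r$values[2, 1], 1 + 99 * 0.25)
  flat <- build_resistance(rast(matrix(7, 3, 3)))
  expect_true(all(flat$values == 1))
  expect_error(build_resistance(rast(matrix(NA_real_, 2, 2))), "valid")
})

test_that("candidate pairs use nearest-edge distance with an inclusive cap", {
  # two 1-cell patches 50 cells apart on a 1 km grid
  mk <- function(gap_cells, cell_km = 1) {
    mask <- matrix(0, 5, gap_cells + 3)
    mask[3, 1] <- 1; mask[3, gap_cells + 2] <- 1
    label_patches(rast(mask, cell_km))
  }
  expect_equal(nrow(candidate_pairs(mk(50), 113)), 1)
  expect_equal(nrow(candidate_pairs(mk(120), 113)), 0)
  exact <- candidate_pairs(mk(112), 113)   # centers exactly 113 km apart
  expect_equal(nrow(exact), 1)                 # exactly at the cap: included
  expect_equal(exact$euclid_km, 113)
  # edge-to-edge, not centroid: a long patch's near edge decides
  mask <- matrix(0, 5, 30)
  mask[3, 1:20] <- 1; mask[3, 25] <- 1
  p <- label_patches(rast(mask))
  expect_equal(candidate_pairs(p, 113)$euclid_km, 5)
})

test_that("uniform resistance gives a straight unit-cost corridor", {
  setup <- two_patch_setup()      # patches in cols 1:5 and 36:40, 1 km cells
  cr <- least_cost_corridor(setup$resistance, setup$patches, 1, 2)
  expect_equal(cr$cwd, 31)        # 31 moves of cost 1 between nearest edges
  expect_equal(cr$length_km, 31)
  expect_equal(cr$euclid_km, 31)
  rows <- cr$path_cells[, "row"]
  expect_true(all(rows == rows[1]))            # straight path
  # symmetry
  cr_ba <- least_cost_corridor(setup$resistance, setup$patches, 2, 1)
  expect_equal(cr_ba$cwd, cr$cwd)
})

test_that("paths route through gaps in impassable walls, matching Dijkstra", {
  nr <- 15; nc <- 21
  mask <- matrix(0, nr, nc)
  mask[7:9, 1:3] <- 1; mask[7:9, 19:21] <- 1
  patches <- label_patches(rast(mask))
  res <- matrix(1, nr, nc)
  res[1:12, 11] <- NA                         # wall with a gap at the bottom
  resistance <- rast(res)
  cr <- least_cost_corridor(resistance, patches, 1, 2)
  expect_true(any(cr$path_cells[, "row"] >= 13))   # routed through the gap
  expect_false(any(is.na(res[cr$path_cells])))
  want <- oracle_lcp_cwd(res, patches$labels, 1, 2, 1)
  expect_equal(cr$cwd, want, tolerance = 1e-9)
  # fully blocking wall -> no corridor
  res2 <- matrix(1, nr, nc); res2[, 11] <- NA
  expect_null(least_cost_corridor(rast(res2), patches, 1, 2))
})

test_that("corridor cost matches an independent Dijkstra on random grids", {
  for (trial in 1:10) {
    set.seed(300 + trial)
    nr <- sample(10:20, 1); nc <- sample(10:20, 1)
    res <- matrix(runif(nr * nc, 1, 100), nr, nc)
    res[runif(nr * nc) < 0.05] <- NA
    mask <- matrix(0, nr, nc)
    mask[1:2, 1:2] <- 1; mask[(nr - 1):nr, (nc - 1):nc] <- 1
    res[mask == 1] <- ifelse(is.na(res[mask == 1]), 1, res[mask == 1])
    patches <- label_patches(rast(mask))
    if (nrow(patches$table) != 2) next
    cr <- least_cost_corridor(rast(res), patches, 1, 2)
    want <- oracle_lcp_cwd(res, patches$labels, 1, 2, 1)
    if (is.null(cr)) {
      expect_true(is.infinite(want))
    } else {
      expect_equal(cr$cwd, want, tolerance = 1e-9)
      expect_gte(cr$cwd, cr$length_km * (1 - 1e-9))  # resistance >= 1
    }
  }
})

test_that("raising a cell's resistance never lowers the corridor cost", {
  set.seed(31)
  setup <- two_patch_setup(resistance_value = 1)
  res <- setup$resistance
  res$values <- matrix(runif(prod(dim(res)), 1, 50), nrow(res$values))
  base <- least_cost_corridor(res, setup$patches, 1, 2)$cwd
  for (k in 1:5) {
    res2 <- res
    cell <- c(sample(nrow(res$values), 1), sample(ncol(res$values), 1))
    res2$values[cell[1], cell[2]] <- res2$values[cell[1], cell[2]] + 30
    expect_gte(least_cost_corridor(res2, setup$patches, 1, 2)$cwd,
               base - 1e-12)
  }
})

test_that("corridors through third patches are pruned", {
  # three collinear patches: A - C - B
  mask <- matrix(0, 5, 30)
  mask[2:4, 1:3] <- 1; mask[2:4, 14:16] <- 1; mask[2:4, 27:29] <- 1
  patches <- label_patches(rast(mask))
  res <- rast(matrix(1, 5, 30))
  net_raw <- build_network(patches, res, max_euclid_km = 113, prune = FALSE)
  net <- build_network(patches, res, max_euclid_km = 113, prune = TRUE)
  expect_equal(nrow(net_raw$edges), 3)
  expect_equal(nrow(net$edges), 2)   # the A-B through-corridor dropped
  # every surviving path avoids third-patch cells
  for (cr in net$corridors) {
    lab <- patches$labels[cr$path_cells]
    expect_true(all(lab %in% c(0L, cr$patch_a, cr$patch_b)))
  }
})

test_that("current-flow centrality ranks cut vertices above leaves", {
  nodes <- c(1, 2, 3)
  edges <- data.frame(patch_a = c(1, 2), patch_b = c(2, 3), cwd = c(2, 2))
  net <- structure(list(nodes = data.frame(patch_id = nodes), edges = edges),
                   class = "connectivity_network")
  cent <- network_centrality(net)
  expect_gt(cent["2"], cent["1"])
  expect_equal(unname(cent["1"]), unname(cent["3"]))
  # arbitrary positive weights preserve the dominance
  edges$cwd <- c(0.7, 3.1)
  net$edges <- edges
  cent2 <- network_centrality(net)
  expect_gt(cent2["2"], max(cent2[c("1", "3")]))
})

test_that("star leaves share the same centrality; isolates score zero", {
  nodes <- 1:6
  edges <- data.frame(patch_a = 1, patch_b = 2:5, cwd = 1.5)
  net <- structure(list(nodes = data.frame(patch_id = nodes), edges = edges),
                   class = "connectivity_network")
  cent <- network_centrality(net)
  expect_equal(unname(cent[as.character(2:5)]), rep(cent[["2"]], 4))
  expect_gt(cent[["1"]], cent[["2"]])
  expect_equal(cent[["6"]], 0)      # isolated patch
})

test_that("centrality matches a Laplacian-pseudoinverse dense solve", {
  for (trial in 1:10) {
    set.seed(400 + trial)
    k <- sample(4:8, 1)
    edges <- random_graph_edges(k)
    net <- structure(list(nodes = data.frame(patch_id = 1:k), edges = edges),
                     class = "connectivity_network")
    got <- network_centrality(net)
    want <- oracle_current_flow(as.character(1:k), edges)
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-8)
  }
})

test_that("corridor summaries count connections and isolates", {
  mask <- matrix(0, 5, 30)
  mask[2:4, 1:3] <- 1; mask[2:4, 10:12] <- 1
  mask[2:4, 27:29] <- 1                    # far patch
  patches <- label_patches(rast(mask))
  res <- rast(matrix(1, 5, 30))
  net <- build_network(patches, res, max_euclid_km = 10)
  s <- corridor_summaries(net)
  expect_equal(s$n_patches, 3)
  expect_equal(s$n_corridors, 1)
  expect_equal(s$n_connected, 2)
  expect_equal(s$n_isolated, 1)
  expect_equal(s$pct_connected, 100 * 2 / 3, tolerance = 1e-12)
  # empty network
  empty <- structure(list(nodes = data.frame(patch_id = integer(0)),
                          edges = data.frame(patch_a = integer(0),
                                             patch_b = integer(0),
                                             euclid_km = numeric(0),
                                             length_km = numeric(0),
                                             cwd = numeric(0)),
                          centrality = numeric(0)),
                     class = "connectivity_network")
  s0 <- corridor_summaries(empty)
  expect_equal(s0$n_corridors, 0)
  expect_equal(s0$length_mean, 0)
})
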