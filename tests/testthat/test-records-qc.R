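classify_one <- function(evidence, source, dept, muni,
                         table = reliability_table()) {
  rec <- data.frame(lon = 0, lat = 0, evidence = evidence, source = source,
                    has_department = dept, has_municipality = muni)
  as.character(classify_reliability(rec, table)$reliability)
}

test_that("reliability is the weakest of credibility and precision", {
  # any low attribute forces low
  expect_equal(classify_one("no_data", "dataset", TRUE, TRUE), "low")
  # all attributes high
  expect_equal(classify_one("preserved_specimen", "peer_reviewed_article",
                            TRUE, TRUE), "high")
  # medium source caps an otherwise high record
  expect_equal(classify_one("preserved_specimen", "museum", TRUE, TRUE),
               "medium")
  # precision dominates: department-only is medium, municipality-only low
  expect_equal(classify_one("machine_observation", "expert_validated",
                            TRUE, FALSE), "medium")
  expect_equal(classify_one("machine_observation", "expert_validated",
                            FALSE, TRUE), "low")
  expect_equal(classify_one("machine_observation", "expert_validated",
                            FALSE, FALSE), "low")
  # the dataset source level is configurable (mixed-provenance entry)
  expect_equal(classify_one("preserved_specimen", "dataset", TRUE, TRUE,
                            reliability_table(dataset_level = "high")),
               "high")
})

test_that("unknown attribute values fail naming the field", {
  rec <- data.frame(lon = 0, lat = 0, evidence = "telepathy",
                    source = "museum", has_department = TRUE,
                    has_municipality = TRUE)
  expect_error(classify_reliability(rec), "evidence")
  rec$evidence <- "no_data"; rec$source <- "blog"
  expect_error(classify_reliability(rec), "source")
})

test_that("filtering drops low records and exact duplicates, keeps order", {
  rec <- records_at(c(1, 1, 2, 3), c(1, 1, 2, 3))
  rec$evidence <- c("preserved_specimen", "preserved_specimen",
                    "no_data", "human_observation")
  rec <- classify_reliability(rec)
  out <- filter_records(rec)
  expect_equal(nrow(out), 2)            # one dup + one low removed
  expect_equal(out$lon, c(1, 3))        # order preserved
  expect_error(filter_records(records_at(0, 0)), "unclassified")
  # idempotence
  expect_identical(filter_records(out), out)
})

test_that("a 535-record set with 147 low/duplicate rows filters to 388", {
  set.seed(99)
  n_low <- 100; n_dup <- 47; n_good <- 535 - n_low - n_dup
  good <- records_at(runif(n_good, -75, -70), runif(n_good, 0, 8))
  low <- records_at(runif(n_low, -75, -70), runif(n_low, 0, 8))
  low$evidence <- "no_data"
  dups <- good[sample(n_good, n_dup, replace = TRUE), ]
  rec <- rbind(good, low, dups)[sample(535), ]
  rec <- classify_reliability(rec)
  expect_equal(nrow(filter_records(rec)), 388)
})

test_that("spatial thinning enforces the minimum distance", {
  # two points 0.5 km apart -> one survivor
  close_pair <- records_north_line(2, 0.5)
  expect_equal(nrow(spatial_thin(close_pair, 1, seed = 1)), 1)
  # 2 km grid spacing -> everything survives
  grid_pts <- records_north_line(10, 2)
  expect_equal(nrow(spatial_thin(grid_pts, 1, seed = 1)), 10)
  # three collinear points 0.8 km apart -> the two endpoints
  trio <- records_north_line(3, 0.8)
  kept <- spatial_thin(trio, 1, seed = 1)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$lat, trio$lat[c(1, 3)])
  expect_error(spatial_thin(trio, -1), "min_dist_km")
})

test_that("thinning is deterministic, idempotent and pairwise-valid", {
  set.seed(5)
  pts <- records_at(-73 + runif(120, 0, 0.05), 4 + runif(120, 0, 0.05))
  t1 <- spatial_thin(pts, 1, seed = 2)
  expect_identical(t1, spatial_thin(pts, 1, seed = 2))
  expect_identical(t1, spatial_thin(t1, 1, seed = 2))
  d <- outer(seq_len(nrow(t1)), seq_len(nrow(t1)), function(i, j) {
    haversine_km(t1$lon[i], t1$lat[i], t1$lon[j], t1$lat[j])
  })
  diag(d) <- Inf
  expect_true(all(d >= 1))
})

test_that("thinning is maximal: no removed point could be re-added", {
  set.seed(8)
  pts <- records_at(-73 + runif(60, 0, 0.03), 4 + runif(60, 0, 0.03))
  kept <- spatial_thin(pts, 1, seed = 3)
  removed <- pts[!paste(pts$lon, pts$lat) %in% paste(kept$lon, kept$lat), ]
  for (i in seq_len(nrow(removed))) {
    d <- haversine_km(removed$lon[i], removed$lat[i], kept$lon, kept$lat)
    expect_lt(min(d), 1)
  }
})

test_that("greedy retention is near the brute-force optimum on small sets", {
  for (trial in 1:10) {
    set.seed(100 + trial)
    n <- sample(6:12, 1)
    pts <- records_at(-73 + runif(n, 0, 0.02), 4 + runif(n, 0, 0.02))
    kept <- spatial_thin(pts, 1, seed = trial)
    best <- oracle_max_thin_size(pts$lon, pts$lat, 1)
    expect_gte(nrow(kept), best - 2)
    expect_lte(nrow(kept), best)
  }
})

test_that("haversine agrees with an independent geodesic implementation", {
  set.seed(2)
  lon1 <- runif(20, -80, -65); lat1 <- runif(20, -5, 12)
  lon2 <- lon1 + runif(20, -0.3, 0.3); lat2 <- lat1 + runif(20, -0.3, 0.3)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371000) / 1000
  expect_equal(haversine_km(lon1, lat1, lon2, lat2), ref, tolerance = 1e-9)
})

test_that("qc_records reports consistent per-stage counts", {
  ls <- generate_landscape(landscape_spec(grid_rows = 40, grid_cols = 40,
                                          seed = 21))
  recs <- generate_records(ls$suitability, n = 300, seed = 21)
  qc <- qc_records(recs, seed = 21)
  expect_equal(unname(qc$report["n_input"]), 300)
  expect_equal(unname(qc$report["n_after_thin"]), nrow(qc$records))
  expect_lte(qc$report["n_after_thin"], qc$report["n_after_filter"])
  expect_true(all(qc$records$reliability != "low"))
})
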