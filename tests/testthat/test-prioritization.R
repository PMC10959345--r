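test_that("per-patch criteria count near-natural and protected cells", {
  mask <- matrix(0, 10, 10); mask[1:10, 1:10] <- 1
  p <- label_patches(rast(mask))
  hfi10 <- rast(matrix(10, 10, 10))
  prot <- rast(matrix(0, 10, 10))
  cent <- setNames(0, "1")
  cr <- compute_criteria(p, hfi10, prot, cent)
  expect_equal(cr$hfi_natural_pct, 100)
  # "under 15" is strict: HFI exactly 15 everywhere counts zero cells
  cr15 <- compute_criteria(p, rast(matrix(15, 10, 10)), prot, cent)
  expect_equal(cr15$hfi_natural_pct, 0)
  # 40 of 100 cells below the cutoff
  m <- matrix(20, 10, 10); m[1:4, ] <- 10
  cr40 <- compute_criteria(p, rast(m), prot, cent)
  expect_equal(cr40$hfi_natural_pct, 40)
  # missing centrality entry resolves to 0
  cr0 <- compute_criteria(p, hfi10, prot, setNames(5, "999"))
  expect_equal(cr0$centrality, 0)
})

test_that("min-max normalization hits 0/1 and degenerates to 0", {
  cr <- data.frame(patch_id = 1:3, hfi_natural_pct = c(2, 4, 6),
                   area_km2 = c(100, 200, 300), protected_pct = c(5, 5, 5),
                   centrality = c(0, 1, 3))
  n <- normalize_criteria(cr)
  expect_equal(n$n_hfi, c(0, 0.5, 1))
  expect_equal(n$n_prot, c(0, 0, 0))       # constant criterion
  expect_equal(n$n_cent, c(0, 1 / 3, 1))
  single <- normalize_criteria(cr[1, ])
  expect_equal(unlist(single[c("n_hfi", "n_prot", "n_cent")],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("ordinal area scores follow the home-range break points", {
  expect_equal(area_score(c(100, 2000, 6000)), c(1L, 2L, 3L))
  expect_equal(area_score(23.5), 1L)
  # boundaries go to the higher score
  expect_equal(area_score(c(1200, 5000)), c(2L, 3L))
  expect_error(area_score(10), "filtered")
})

test_that("category boundaries follow the strict/inclusive threshold rules", {
  eps <- 1e-9
  totals <- c(2.0, 2.0 + eps, 3.0, 3.0 + eps, 4.0, 4.0 + eps)
  expect_equal(as.character(classify_priority(totals)),
               c("JPRA_II", "JPRA_I", "JPRA_I", "JPCA_II", "JPCA_II",
                 "JPCA_I"))
  expect_equal(as.character(classify_priority(4.5)), "JPCA_I")
  expect_equal(as.character(classify_priority(1)), "JPRA_II")
  # partition of [1, 6] is exhaustive and mutually exclusive
  grid <- seq(1, 6, by = 0.01)
  cats <- classify_priority(grid)
  expect_false(anyNA(cats))
  expect_equal(length(unique(cats)), 4)
})

test_that("an engineered dominant patch is JPCA I, a marginal one JPRA II", {
  cr <- data.frame(
    patch_id = 1:3,
    hfi_natural_pct = c(95, 10, 20),
    area_km2 = c(6000, 30, 400),
    protected_pct = c(80, 0, 10),
    centrality = c(40, 0, 5))
  sc <- prioritize(cr)
  expect_equal(sc$total[1], 3 + 3)            # max on every criterion
  expect_equal(as.character(sc$category[1]), "JPCA_I")
  expect_equal(sc$total[2], 1)                # min on every criterion
  expect_equal(as.character(sc$category[2]), "JPRA_II")
})

test_that("identical patches fall back to the area score alone", {
  cr <- data.frame(patch_id = 1:4, hfi_natural_pct = 50,
                   area_km2 = c(100, 100, 2000, 6000), protected_pct = 20,
                   centrality = 3)
  sc <- prioritize(cr)
  expect_equal(sc$total, as.numeric(sc$area_score))
  expect_equal(as.character(sc$category), c("JPRA_II", "JPRA_II", "JPRA_II",
                                            "JPRA_I"))
})

test_that("raising one criterion never demotes a patch", {
  set.seed(12)
  base <- data.frame(patch_id = 1:6,
                     hfi_natural_pct = runif(6, 0, 100),
                     area_km2 = runif(6, 24, 8000),
                     protected_pct = runif(6, 0, 100),
                     centrality = runif(6, 0, 50))
  cat_rank <- function(x) match(as.character(x),
                                c("JPRA_II", "JPRA_I", "JPCA_II", "JPCA_I"))
  sc0 <- prioritize(base)
  for (col in c("hfi_natural_pct", "protected_pct", "centrality",
                "area_km2")) {
    for (i in 1:6) {
      up <- base
      up[i, col] <- up[i, col] * 1.5 + 10
      if (col %in% c("hfi_natural_pct", "protected_pct")) {
        up[i, col] <- min(up[i, col], 100)
      }
      sc1 <- prioritize(up)
      expect_gte(cat_rank(sc1$category)[i], cat_rank(sc0$category)[i])
    }
  }
})

test_that("scores are invariant to patch input order", {
  set.seed(13)
  cr <- data.frame(patch_id = 1:8, hfi_natural_pct = runif(8, 0, 100),
                   area_km2 = runif(8, 24, 9000),
                   protected_pct = runif(8, 0, 100),
                   centrality = runif(8, 0, 10))
  sc <- prioritize(cr)
  perm <- sample(8)
  sc_perm <- prioritize(cr[perm, ])
  reord <- sc_perm[match(sc$patch_id, sc_perm$patch_id), ]
  rownames(reord) <- NULL
  expect_equal(reord$total, sc$total)
  expect_equal(as.character(reord$category), as.character(sc$category))
})

test_that("category counts add up", {
  cr <- data.frame(patch_id = 1:5, hfi_natural_pct = c(90, 80, 10, 5, 0),
                   area_km2 = c(6000, 2000, 100, 50, 30),
                   protected_pct = c(90, 50, 5, 0, 0),
                   centrality = c(10, 8, 1, 0, 0))
  counts <- priority_counts(prioritize(cr))
  expect_equal(unname(counts["JPCA"] + counts["JPRA"]), 5)
  expect_equal(unname(counts["JPCA"]),
               unname(counts["JPCA_I"] + counts["JPCA_II"]))
})
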