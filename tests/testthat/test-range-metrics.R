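toy_resamples <- function() {
  occ <- toy_occurrence(reads = 6000)
  cfg <- run_config(n_slices = 1, window_width_slices = 1, n_iterations = 2,
                    rng_seed = 4)
  rarefy_dataset(occ, cfg)
}

test_that("richness counts distinct taxa across lakes of a slice", {
  rs <- toy_resamples()
  expect_equal(richness_per_slice(rs, 1, 1), 4)  # taxa A-D
  # one taxon everywhere is richness 1
  occ1 <- data.frame(lake_id = sprintf("L%d", 1:7), slice_index = 1L,
                     taxon_id = "A", family = "F", reads = 6000L)
  rs1 <- rarefy_dataset(occ1, run_config(n_slices = 1,
                                         window_width_slices = 1,
                                         n_iterations = 1, rng_seed = 1))
  expect_equal(richness_per_slice(rs1, 1, 1), 1)
})

test_that("area of occupancy is the occupied-lake count", {
  rs <- toy_resamples()
  aoo <- aoo_range(rs, 1, 1)
  expect_equal(aoo[["A"]], 3)
  expect_equal(aoo[["B"]], 2)
  expect_equal(aoo[["C"]], 1)
  expect_equal(aoo[["D"]], 3)
  expect_equal(mean(aoo), 9 / 4)
})

test_that("the equal-area projection preserves distances and centring", {
  skip_if_not_installed("geosphere")
  one <- project_lakes(data.frame(lake_id = "L", lon = 130, lat = 65))
  expect_equal(c(one$x, one$y), c(0, 0), tolerance = 1e-9)

  reg <- data.frame(lake_id = c("A", "B"), lon = c(120, 121.5), lat = c(64, 64.4))
  pr <- project_lakes(reg)
  planar <- sqrt(diff(pr$x)^2 + diff(pr$y)^2)
  geo <- geosphere::distGeo(c(120, 64), c(121.5, 64.4))
  expect_lt(abs(planar - geo) / geo, 0.01)

  # centre (hence projection) is order-invariant
  pr2 <- project_lakes(reg[2:1, ])
  expect_equal(pr2$x[2:1], pr$x, tolerance = 1e-9)
})

test_that("degenerate extent-of-occurrence cases follow the point/segment rules", {
  reg <- toy_lakes()
  pr <- project_lakes(reg)
  g <- make_grid(pr, 200)
  # one lake: exactly its containing cell
  expect_equal(eoo_range("L1", g, pr), 200^2)
  # every lake falls in exactly one cell
  cells <- paleorange:::cell_of(g, pr$x, pr$y)
  expect_equal(nrow(cells), 7)
  # two lakes forced into one cell
  reg2 <- data.frame(lake_id = c("a", "b"), lon = c(120, 120.1),
                     lat = c(64, 64.02))
  pr2 <- project_lakes(reg2)
  g2 <- make_grid(pr2, 200)
  expect_equal(eoo_range(c("a", "b"), g2, pr2), 200^2)
  expect_error(eoo_range(character(0), g2, pr2), "empty")
})

test_that("extent of occurrence is bounded and monotone in the occupied set", {
  reg <- generate_lakes(9, seed = 31)
  pr <- project_lakes(reg)
  g <- make_grid(pr, 200)
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    sub <- sample(reg$lake_id, k)
    a <- eoo_range(sub, g, pr)
    expect_gte(a, g$cell_area_km2)
    expect_lte(a, g$nx * g$ny * g$cell_area_km2)
    # adding a lake never shrinks the hull's cell set
    extra <- sample(setdiff(reg$lake_id, sub), 1)
    cells_small <- paleorange:::cell_key(eoo_cells(sub, g, pr))
    cells_big <- paleorange:::cell_key(eoo_cells(c(sub, extra), g, pr))
    expect_true(all(cells_small %in% cells_big))
  }
})

test_that("hull cell sets match the rasterization oracle on random sets", {
  skip_if_not_installed("mgcv")
  reg <- generate_lakes(12, seed = 77,
                        bbox = c(lon_min = 110, lon_max = 128,
                                 lat_min = 60, lat_max = 68))
  pr <- project_lakes(reg)
  g <- make_grid(pr, 200)
  set.seed(77)
  for (i in 1:25) {
    sub <- sample(reg$lake_id, sample(1:12, 1))
    mine <- sort(paleorange:::cell_key(eoo_cells(sub, g, pr)))
    oracle <- sort(oracle_eoo_cells(sub, g, pr))
    expect_identical(mine, oracle)
  }
})

test_that("slice summaries reproduce a hand-computed toy", {
  occ <- toy_occurrence(reads = 6000)
  cfg <- run_config(n_slices = 1, window_width_slices = 1, n_iterations = 3,
                    rng_seed = 12)
  rs <- rarefy_dataset(occ, cfg)
  sm <- slice_range_summaries(rs, toy_lakes(), cfg)
  expect_equal(nrow(sm), 3)           # one record per (iteration, slice)
  expect_equal(sm$richness, rep(4L, 3))
  expect_equal(sm$mean_range_aoo, rep(9 / 4, 3))  # (3 + 2 + 1 + 3) / 4
  # EOO mean equals the average of the four taxon hull areas
  pr <- project_lakes(toy_lakes())
  g <- make_grid(pr, cfg$grid_cell_km)
  areas <- c(eoo_range(c("L1", "L2", "L3"), g, pr),
             eoo_range(c("L2", "L4"), g, pr),
             eoo_range("L5", g, pr),
             eoo_range(c("L5", "L6", "L7"), g, pr))
  expect_equal(sm$mean_range_eoo, rep(mean(areas), 3))
})

test_that("empty slices yield zero richness and missing means", {
  occ <- toy_occurrence(reads = 6000)  # slice 1 only
  cfg <- run_config(n_slices = 3, window_width_slices = 2, n_iterations = 2,
                    rng_seed = 5)
  rs <- rarefy_dataset(occ, cfg)
  sm <- slice_range_summaries(rs, toy_lakes(), cfg)
  empty <- sm[sm$slice > 1, ]
  expect_true(all(empty$richness == 0))
  expect_true(all(is.na(empty$mean_range_aoo)))
  expect_true(all(is.na(empty$mean_range_eoo)))
})

test_that("doubling read depth leaves expected rarefied shares unchanged", {
  counts <- c(8000L, 5000L, 2000L, 1000L)
  set.seed(9)
  m1 <- rowMeans(replicate(3000, rarefy_sample(counts, 5000)))
  m2 <- rowMeans(replicate(3000, rarefy_sample(2L * counts, 5000)))
  expect_equal(m1, m2, tolerance = 0.03)
})

test_that("AOO and EOO range means are rank-concordant across slices", {
  run <- default_run()
  sm <- run$sm[run$sm$iteration == 1 & run$sm$richness > 0, ]
  rho <- cor(sm$mean_range_aoo, sm$mean_range_eoo, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("grid-cell statistics count ranges and recover built-in structure", {
  pts <- data.frame(taxon = c("t1", "t1", "t1", "t2", "t3"),
                    lon = c(100, 104, 108, 100, 100),
                    lat = c(60, 60, 60, 60, 60))
  st <- grid_cell_stats(pts, cell_km = 200)
  expect_equal(st$per_taxon$range_cells[st$per_taxon$taxon == "t1"], 3)
  cell_t2 <- st$per_cell[st$per_cell$richness == 3, ]
  expect_equal(cell_t2$mean_range_cells, (3 + 1 + 1) / 3)

  # richness high where ranges are small: cell-level slope comes out negative
  set.seed(1)
  wide <- expand.grid(taxon = c("w1", "w2"), cell = 0:5)
  endem <- data.frame(taxon = sprintf("e%d", 1:12),
                      cell = rep(0:2, each = 4))
  occ <- rbind(wide[, c("taxon", "cell")], endem)
  occ$lon <- 100 + occ$cell * 4   # ~4 degrees per 200 km cell at 60N
  occ$lat <- 60
  st2 <- grid_cell_stats(occ, cell_km = 200)
  fit <- fit_linear(data.frame(range = st2$per_cell$mean_range_cells,
                               richness = st2$per_cell$richness))
  expect_lt(fit$coefficients[2], 0)
})
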