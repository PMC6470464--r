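region <- default_region(side_km = 10)

test_that("grid cells are congruent regular hexagons of the requested size", {
  R <- 580  # ~100 cells over a 10 km square
  grid <- build_grid(region, R)
  expect_gt(nrow(grid$cells), 100)
  areas <- vapply(seq_len(min(nrow(grid$cells), 50)), function(i) {
    abs(hexdash:::polygon_area(
      hexdash:::hex_vertices(grid$cells$cx[i], grid$cells$cy[i], R,
                             "flat_top")))
  }, numeric(1))
  expect_true(all(abs(areas - hex_cell_area(R)) / hex_cell_area(R) < 1e-9))
})

test_that("grid construction is deterministic", {
  g1 <- build_grid(region, 700)
  g2 <- build_grid(region, 700)
  expect_identical(g1$cells, g2$cells)
})

test_that("an oversized circumradius is a configuration error", {
  expect_error(build_grid(region, 50000), "configuration error")
  expect_error(build_grid(region, -1), "configuration error")
})

test_that("cell interiors are pairwise disjoint (clipping oracle)", {
  small <- default_region(side_km = 3)
  grid <- build_grid(small, 900)
  n <- nrow(grid$cells)
  hexes <- lapply(seq_len(n), function(i) {
    hexdash:::hex_vertices(grid$cells$cx[i], grid$cells$cy[i],
                           grid$circumradius, grid$orientation)
  })
  cell_area <- hex_cell_area(grid$circumradius)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_lt(convex_clip_area(hexes[[i]], hexes[[j]]) / cell_area, 1e-9)
    }
  }
})

test_that("a point at a cell centroid is assigned to that cell", {
  for (orient in c("flat_top", "pointy_top")) {
    grid <- build_grid(region, 800, orient)
    i <- which(grid$cells$q == 2 & grid$cells$r == -1)
    asg <- assign_points(grid, cbind(grid$cells$cx[i], grid$cells$cy[i]))
    expect_equal(c(asg$q, asg$r), c(2, -1))
  }
})

test_that("edge and corner ties break to the lexicographically smaller key", {
  grid <- build_grid(region, 1000)
  R <- grid$circumradius
  # midpoint of the edge shared by (0,0) and (1,0), flat-top layout
  edge_mid <- cbind(0.75 * R, sqrt(3) * R / 4)
  asg <- assign_points(grid, edge_mid)
  expect_equal(c(asg$q, asg$r), c(0, 0))
  # shared corner of (0,0), (0,1) and (1,0): a vertex of all three hexes
  corner <- cbind(0.5 * R, sqrt(3) * R / 2)
  asg2 <- assign_points(grid, corner)
  expect_equal(c(asg2$q, asg2$r), c(0, 0))
})

test_that("analytic assignment matches brute-force nearest-center", {
  for (orient in c("flat_top", "pointy_top")) {
    grid <- build_grid(region, 900, orient)
    set.seed(5)
    pts <- cbind(runif(1000, grid$bbox["xmin"], grid$bbox["xmax"]),
                 runif(1000, grid$bbox["ymin"], grid$bbox["ymax"]))
    asg <- assign_points(grid, pts)
    oracle <- brute_assign(grid, pts)
    expect_identical(cbind(asg$q, asg$r), oracle)
  }
})

test_that("a point outside grid coverage raises an assignment error", {
  grid <- build_grid(region, 800)
  expect_error(assign_points(grid, cbind(1e6, 1e6)), "assignment error")
})

test_that("aggregation conserves counts and matches a per-point tally", {
  b <- small_bundle(600, seed = 9)
  grid <- build_grid(b$region, 1200)
  agg <- aggregate_bundle(grid, b)
  expect_equal(sum(agg$cells$participant_count), 600)

  # independent per-point tally from the brute-force oracle
  xy <- project_planar(cbind(b$participants$lon, b$participants$lat),
                       grid$center)
  oracle <- brute_assign(grid, xy)
  key <- paste(oracle[, 1], oracle[, 2])
  tab <- table(key)
  agg_key <- paste(agg$cells$q, agg$cells$r)
  expect_equal(agg$cells$participant_count[match(names(tab), agg_key)],
               as.integer(tab))
  # cells not in the tally are empty
  expect_true(all(agg$cells$participant_count[!agg_key %in% names(tab)] == 0))

  # categorical tallies per cell sum to the cell count
  sex_t <- agg$tallies[agg$tallies$variable == "sex", ]
  per_cell <- tapply(sex_t$count, paste(sex_t$q, sex_t$r), sum)
  expect_equal(as.vector(per_cell[agg_key[agg$cells$participant_count > 0]]),
               agg$cells$participant_count[agg$cells$participant_count > 0])
})

test_that("numerators never exceed denominators nor the cell count", {
  b <- small_bundle(400, seed = 2)
  grid <- build_grid(b$region, 1500)
  agg <- aggregate_bundle(grid, b)
  ic <- agg$indicator_counts
  expect_true(all(ic$numerator <= ic$denominator))
  counts <- agg$cells$participant_count[
    match(paste(ic$q, ic$r), paste(agg$cells$q, agg$cells$r))]
  expect_true(all(ic$denominator <= counts))
})

test_that("aggregation is idempotent", {
  b <- small_bundle(300, seed = 4)
  grid <- build_grid(b$region, 1500)
  ind <- cascade_indicators()
  expect_identical(aggregate_bundle(grid, b, ind),
                   aggregate_bundle(grid, b, ind))
})

test_that("suppression keeps exactly the cells at or above the floor", {
  b <- small_bundle(500, seed = 3)
  grid <- build_grid(b$region, 1000)
  agg <- aggregate_bundle(grid, b)

  d1 <- suppress_cells(agg, 1)
  expect_true(all(d1$cells$participant_count >= 1))
  expect_equal(nrow(d1$cells), sum(agg$cells$participant_count >= 1))
  expect_equal(d1$suppression$hidden_cells, 0)

  # min_count = 0 behaves like 1: empty cells are never shown
  d0 <- suppress_cells(agg, 0)
  expect_identical(d0$cells, d1$cells)

  d5 <- suppress_cells(agg, 5)
  below <- agg$cells$participant_count > 0 & agg$cells$participant_count < 5
  expect_equal(d5$suppression$hidden_cells, sum(below))
  expect_equal(d5$suppression$hidden_participants,
               sum(agg$cells$participant_count[below]))
  expect_false(any(paste(agg$cells$q[below], agg$cells$r[below]) %in%
                     paste(d5$cells$q, d5$cells$r)))
})

test_that("displayable cells serialize to GeoJSON at hex granularity only", {
  b <- small_bundle(300, seed = 8)
  grid <- build_grid(b$region, 1500)
  disp <- suppress_cells(aggregate_bundle(grid, b), 1)
  gj <- display_to_geojson(disp)
  expect_equal(length(gj$features), nrow(disp$cells))
  counts <- vapply(gj$features, function(f) f$properties$participant_count,
                   numeric(1))
  expect_true(all(counts >= 1))
  f1 <- gj$features[[1]]
  expect_true(all(c("cell_q", "cell_r", "participant_count",
                    "hiv_prevalence_numerator", "hiv_prevalence_denominator")
                  %in% names(f1$properties)))
  expect_equal(length(f1$geometry$coordinates[[1]]), 7)  # closed hex ring
})
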