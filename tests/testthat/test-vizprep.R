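test_that("classification reproduces the closed-form break positions", {
  v <- as.numeric(1:100)
  eq <- classify_values(v, 5, "equal_interval")
  expect_equal(eq$breaks[2:5], c(20.8, 40.6, 60.4, 80.2))
  qt <- classify_values(v, 5, "quantile")
  expect_equal(as.integer(table(qt$classes)), rep(20L, 5))
})

test_that("degenerate all-equal input collapses to one flagged class", {
  out <- classify_values(rep(7, 20), 5, "quantile")
  expect_true(out$degenerate)
  expect_equal(out$n_classes, 1)
  expect_true(all(out$classes == 1))
})

test_that("every value lies within its assigned class interval", {
  set.seed(30)
  for (rep_i in 1:5) {
    v <- c(rnorm(80), NA, NA)
    for (method in c("quantile", "equal_interval")) {
      out <- classify_values(v, 5, method)
      expect_equal(out$excluded, c(81L, 82L))
      ok <- !is.na(v)
      lo <- out$breaks[out$classes[ok]]
      hi <- out$breaks[out$classes[ok] + 1]
      expect_true(all(v[ok] >= lo - 1e-12 & v[ok] <= hi + 1e-12))
      if (method == "quantile") {
        occ <- table(out$classes[ok])
        expect_lte(max(occ) - min(occ), 1)
      }
    }
  }
})

test_that("classification is permutation-invariant in cell order", {
  set.seed(31)
  v <- runif(60)
  perm <- sample(60)
  a <- classify_values(v, 4, "quantile")
  b <- classify_values(v[perm], 4, "quantile")
  expect_equal(a$breaks, b$breaks)
  expect_equal(a$classes[perm], b$classes)
})

test_that("chart payloads conserve their base populations", {
  p <- synth_generate(synth_params(n_participants = 800, seed = 17))$participants
  pyr <- pyramid_payload(p)
  expect_equal(sum(pyr$female_counts) + sum(pyr$male_counts), nrow(p))
  expect_equal(pyr$base_size, nrow(p))

  st <- stacked_bar_payload(p)
  expect_equal(sum(st$bin_sizes), nrow(p))
  nonempty <- st$bin_sizes > 0
  expect_true(all(abs(st$positive_fraction[nonempty] +
                        st$negative_fraction[nonempty] - 1) <= 0.011))

  tm <- treemap_payload(p, "education")
  expect_equal(sum(vapply(tm$tiles, function(t) t$count, numeric(1))), nrow(p))
  expect_equal(sum(vapply(tm$tiles, function(t) t$proportion, numeric(1))), 1,
               tolerance = 1e-3)
  counts <- vapply(tm$tiles, function(t) t$count, numeric(1))
  expect_true(all(diff(counts) <= 0))  # descending tile order
})

test_that("switching normalization mode changes bases, not label sets", {
  p <- synth_generate(synth_params(n_participants = 600, seed = 18))$participants
  catalog <- cascade_indicators()
  t_tot <- treemap_payload(p, "education", "total_population")
  t_ind <- treemap_payload(p, "education", "indicator_population",
                           catalog$hiv_prevalence)
  labs <- function(tm) sort(vapply(tm$tiles, function(t) t$label, character(1)))
  expect_equal(labs(t_tot), labs(t_ind))
  expect_equal(t_ind$base_size, sum(p$hiv_positive))
})

# one materialized pipeline shared by the payload tests
bundle <- synth_generate(synth_params(n_participants = 1500, seed = 19))
catalog <- cascade_indicators()
grid <- build_grid(bundle$region, 1200)
agg <- aggregate_bundle(grid, bundle, catalog)
disp <- suppress_cells(agg, 1)
gv <- compute_cascade(catalog, bundle$participants)
top <- which.max(disp$cells$participant_count)
cell <- c(disp$cells$q[top], disp$cells$r[top])

test_that("the overview payload has donuts and map, footer only on selection", {
  ov <- build_overview_payload(disp, gv, catalog)
  types <- vapply(ov$sections, function(s) s$type, character(1))
  expect_equal(types, c("choropleth", "donuts"))

  ov2 <- build_overview_payload(disp, gv, catalog, selected_cell = cell)
  types2 <- vapply(ov2$sections, function(s) s$type, character(1))
  expect_true("footer_comparison" %in% types2)
  footer <- ov2$sections[[which(types2 == "footer_comparison")]]
  expect_equal(footer$participant_count, max(disp$cells$participant_count))

  # footer rows equal the compare_local_global output for that cell
  cv <- hexdash:::cell_cascade_values(disp, catalog, cell)
  want <- bar_comparison_payload(compare_local_global(catalog, cv, gv))
  expect_identical(footer$comparison, want)

  # conservation: displayed participants = bundle size - suppressed
  geo <- ov2$sections[[1]]$geojson
  shown <- sum(vapply(geo$features,
                      function(f) f$properties$participant_count, numeric(1)))
  expect_equal(shown,
               nrow(bundle$participants) - disp$suppression$hidden_participants)
})

test_that("selecting an absent or suppressed cell is a selection error", {
  expect_error(build_overview_payload(disp, gv, catalog,
                                      selected_cell = c(999, 999)),
               "selection error")
  expect_error(build_analysis_payload(disp, agg, bundle, c(999, 999), catalog),
               "selection error")
})

test_that("the analysis payload honors the chart menu and conserves counts", {
  an <- build_analysis_payload(disp, agg, bundle, cell, catalog,
                               chart_menu = "pyramid")
  expl <- an$sections[[1]]
  expect_equal(length(expl$charts), 1)
  pyr <- expl$charts[[1]]
  cell_n <- max(disp$cells$participant_count)
  expect_equal(sum(pyr$female_counts) + sum(pyr$male_counts), cell_n)

  key <- an$sections[[4]]
  expect_equal(key$type, "key_numbers")
  expect_equal(key$participant_count, cell_n)
  expect_equal(key$female + key$male, cell_n)

  expect_error(build_analysis_payload(disp, agg, bundle, cell, catalog,
                                      chart_menu = c("pyramid", "sparkline")),
               "sparkline.*pyramid|valid charts")
})

test_that("indicator-population treemaps use the cell's indicator base", {
  an <- build_analysis_payload(disp, agg, bundle, cell, catalog,
                               chart_menu = "treemap_education",
                               normalization = "indicator_population",
                               indicator_filter = "art_of_diagnosed")
  tm <- an$sections[[1]]$charts[[1]]
  ic <- disp$indicator_counts
  on_art_in_cell <- ic$numerator[ic$q == cell[1] & ic$r == cell[2] &
                                   ic$indicator == "art_of_diagnosed"]
  expect_equal(tm$base_size, on_art_in_cell)
})

test_that("scatter points are hex cells, one per displayable defined cell", {
  sc <- scatter_payload(disp, catalog, "hiv_prevalence", "suppressed_of_art")
  expect_lte(length(sc$points), nrow(disp$cells))
  expect_true(all(vapply(sc$points, function(p)
    all(c("cell_q", "cell_r", "x", "y") %in% names(p)), logical(1))))
})

test_that("payloads serialize to the documented JSON envelope", {
  ov <- build_overview_payload(disp, gv, catalog, data_version = "v1",
                               generated_at = "t0")
  doc <- jsonlite::fromJSON(payload_json(ov), simplifyVector = FALSE)
  expect_equal(names(doc)[1:4],
               c("page", "sections", "generated_at", "data_version"))
  expect_equal(doc$page, "overview")
  expect_equal(doc$data_version, "v1")
  expect_true(all(vapply(doc$sections, function(s) !is.null(s$type),
                         logical(1))))
})
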