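# Uniform hexagonal tessellation of the study region, point-to-cell
# assignment, per-cell aggregation and the privacy floor. Cells are indexed
# by axial coordinates (q, r); assignment uses analytic cube rounding, which
# is O(1) per point and equivalent to nearest-center (the brute-force
# nearest-center search is kept as a test oracle, not used in production).

.axial_neighbors <- matrix(c(1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0, 1),
                           ncol = 2, byrow = TRUE)

# axial (q, r) -> planar center, vectorized
axial_to_xy <- function(q, r, circumradius, orientation) {
  R <- circumradius
  if (orientation == "flat_top") {
    cbind(1.5 * R * q, sqrt(3) * R * (r + q / 2))
  } else {
    cbind(sqrt(3) * R * (q + r / 2), 1.5 * R * r)
  }
}

# planar point -> fractional axial coordinates
xy_to_axial_frac <- function(x, y, circumradius, orientation) {
  R <- circumradius
  if (orientation == "flat_top") {
    cbind((2 / 3) * x / R, (-x / 3 + sqrt(3) / 3 * y) / R)
  } else {
    cbind((sqrt(3) / 3 * x - y / 3) / R, (2 / 3) * y / R)
  }
}

# standard cube rounding of fractional axial coordinates
axial_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  cbind(q = as.integer(q), r = as.integer(r))
}

# vertices of one hexagon as a 6x2 matrix
hex_vertices <- function(cx, cy, circumradius, orientation) {
  offset <- if (orientation == "flat_top") 0 else pi / 6
  ang <- offset + (0:5) * pi / 3
  cbind(cx + circumradius * cos(ang), cy + circumradius * sin(ang))
}

#' Area of a regular hexagon with the given circumradius
#' @param circumradius center-to-corner distance.
#' @return area in squared units of the circumradius.
#' @export
hex_cell_area <- function(circumradius) 3 * sqrt(3) / 2 * circumradius^2

#' Build a uniform hexagonal grid over a study region
#'
#' Tessellates the region's bounding box (plus one ring of margin) with
#' congruent regular hexagons in a local equal-area planar projection
#' centered on the region. Two calls with identical inputs give identical
#' cell key sets.
#'
#' @param region a [study_region()].
#' @param cell_circumradius hexagon center-to-corner distance in meters.
#' @param orientation `"flat_top"` (default) or `"pointy_top"`.
#' @return object of class `hex_grid`: `cells` (data.frame `q`, `r`, `cx`,
#'   `cy` in meters), `circumradius`, `orientation`, `center` (lon/lat
#'   projection center), `bbox` (planar region bounding box).
#' @export
build_grid <- function(region, cell_circumradius,
                       orientation = c("flat_top", "pointy_top")) {
  stopifnot(inherits(region, "study_region"))
  orientation <- match.arg(orientation)
  if (!is.numeric(cell_circumradius) || cell_circumradius <= 0) {
    stop("configuration error: cell_circumradius must be > 0")
  }
  bnd <- project_planar(region$boundary, region$center)
  bbox <- c(xmin = min(bnd[, 1]), xmax = max(bnd[, 1]),
            ymin = min(bnd[, 2]), ymax = max(bnd[, 2]))
  short_side <- min(bbox["xmax"] - bbox["xmin"], bbox["ymax"] - bbox["ymin"])
  if (cell_circumradius > short_side) {
    stop("configuration error: cell_circumradius (", cell_circumradius,
         " m) exceeds the region's shortest bounding-box side (",
         round(short_side), " m); the grid would be degenerate")
  }
  margin <- 2.5 * cell_circumradius  # bbox plus one ring of cells
  corners <- rbind(
    c(bbox["xmin"] - margin, bbox["ymin"] - margin),
    c(bbox["xmax"] + margin, bbox["ymin"] - margin),
    c(bbox["xmax"] + margin, bbox["ymax"] + margin),
    c(bbox["xmin"] - margin, bbox["ymax"] + margin)
  )
  fr <- xy_to_axial_frac(corners[, 1], corners[, 2], cell_circumradius, orientation)
  qr <- expand.grid(q = (floor(min(fr[, 1])) - 2):(ceiling(max(fr[, 1])) + 2),
                    r = (floor(min(fr[, 2])) - 2):(ceiling(max(fr[, 2])) + 2))
  xy <- axial_to_xy(qr$q, qr$r, cell_circumradius, orientation)
  keep <- xy[, 1] >= bbox["xmin"] - margin & xy[, 1] <= bbox["xmax"] + margin &
          xy[, 2] >= bbox["ymin"] - margin & xy[, 2] <= bbox["ymax"] + margin
  cells <- data.frame(q = as.integer(qr$q[keep]), r = as.integer(qr$r[keep]),
                      cx = xy[keep, 1], cy = xy[keep, 2])
  cells <- cells[order(cells$q, cells$r), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, circumradius = cell_circumradius,
                 orientation = orientation, center = region$center,
                 bbox = bbox),
            class = "hex_grid")
}

.cell_key <- function(q, r) paste(q, r, sep = ",")

#' Assign planar points to hexagonal cells
#'
#' Each point maps to the cell whose center is nearest, computed analytically
#' via cube rounding. Points equidistant from several centers (cell edges and
#' corners) break the tie deterministically toward the lexicographically
#' smallest (q, r).
#'
#' @param grid a [build_grid()] result.
#' @param points two-column matrix of planar x/y in the grid's projection.
#' @return data.frame with one row per point: `point` (index), `q`, `r`.
#' @export
assign_points <- function(grid, points) {
  stopifnot(inherits(grid, "hex_grid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (n == 0) return(data.frame(point = integer(), q = integer(), r = integer()))
  fr <- xy_to_axial_frac(points[, 1], points[, 2], grid$circumradius,
                         grid$orientation)
  key0 <- axial_round(fr[, 1], fr[, 2])
  q <- key0[, 1]; r <- key0[, 2]
  tol <- 1e-9 * grid$circumradius

  # exact-tie handling: compare against the 6 neighbors, prefer the
  # lexicographically smallest key among centers within tolerance of minimum
  cand_q <- cbind(q, outer(q, .axial_neighbors[, 1], `+`))
  cand_r <- cbind(r, outer(r, .axial_neighbors[, 2], `+`))
  best_q <- q; best_r <- r
  best_d <- sqrt(rowSums((axial_to_xy(q, r, grid$circumradius, grid$orientation) -
                            points)^2))
  for (k in 2:7) {
    cxy <- axial_to_xy(cand_q[, k], cand_r[, k], grid$circumradius,
                       grid$orientation)
    d <- sqrt(rowSums((cxy - points)^2))
    tie <- abs(d - best_d) <= tol
    closer <- d < best_d - tol
    swap_tie <- tie & (cand_q[, k] < best_q |
                         (cand_q[, k] == best_q & cand_r[, k] < best_r))
    sel <- closer | swap_tie
    best_q[sel] <- cand_q[sel, k]
    best_r[sel] <- cand_r[sel, k]
    best_d[closer] <- d[closer]
  }

  grid_keys <- .cell_key(grid$cells$q, grid$cells$r)
  miss <- !(.cell_key(best_q, best_r) %in% grid_keys)
  if (any(miss)) {
    i <- which(miss)[1]
    stop("assignment error: point ", i, " at (", points[i, 1], ", ",
         points[i, 2], ") lies outside grid coverage")
  }
  data.frame(point = seq_len(n), q = as.integer(best_q),
             r = as.integer(best_r))
}

#' Aggregate a bundle onto a hexagonal grid
#'
#' Projects participants into the grid's planar system, assigns each to a
#' cell and tallies per-cell participant counts, per-indicator numerators
#' and denominators, and categorical tallies (sex, education, relationship
#' status, employment). Counts are conserved: cell counts sum to the bundle
#' size. All grid cells are present, including empty ones; suppression is a
#' separate, later step ([suppress_cells()]).
#'
#' @param grid a [build_grid()] result.
#' @param bundle a [dataset_bundle()].
#' @param indicators list of [indicator_definition()]s (defaults to the
#'   built-in treatment-cascade catalog).
#' @return object of class `hex_aggregates`: `cells` (q, r, cx, cy,
#'   participant_count), `indicator_counts` (q, r, indicator, numerator,
#'   denominator), `tallies` (q, r, variable, label, count), `assignment`
#'   (per-participant cell key), `n_participants`, plus the `grid`.
#' @export
aggregate_bundle <- function(grid, bundle, indicators = cascade_indicators()) {
  stopifnot(inherits(grid, "hex_grid"), inherits(bundle, "dataset_bundle"))
  p <- bundle$participants
  xy <- project_planar(cbind(p$lon, p$lat), grid$center)
  asg <- assign_points(grid, xy)
  key <- .cell_key(asg$q, asg$r)
  grid_keys <- .cell_key(grid$cells$q, grid$cells$r)
  idx <- match(key, grid_keys)

  counts <- tabulate(idx, nbins = nrow(grid$cells))
  cells <- data.frame(grid$cells, participant_count = as.integer(counts))

  ind_rows <- lapply(indicators, function(defn) {
    num <- indicator_numerator(defn, p)
    den <- indicator_denominator(defn, p)
    data.frame(
      q = grid$cells$q, r = grid$cells$r, indicator = defn$name,
      numerator = as.integer(tabulate(idx[num], nbins = nrow(grid$cells))),
      denominator = as.integer(tabulate(idx[den], nbins = nrow(grid$cells))),
      stringsAsFactors = FALSE
    )
  })
  indicator_counts <- do.call(rbind, ind_rows)
  rownames(indicator_counts) <- NULL

  tally_rows <- lapply(c("sex", .cat_cols), function(v) {
    tt <- table(cell = factor(idx, levels = seq_len(nrow(grid$cells))),
                label = p[[v]])
    df <- as.data.frame(tt, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    ci <- as.integer(df$cell)
    data.frame(q = grid$cells$q[ci], r = grid$cells$r[ci], variable = v,
               label = df$label, count = as.integer(df$Freq),
               stringsAsFactors = FALSE)
  })
  tallies <- do.call(rbind, tally_rows)
  rownames(tallies) <- NULL

  structure(list(grid = grid, cells = cells,
                 indicator_counts = indicator_counts, tallies = tallies,
                 assignment = asg, n_participants = nrow(p),
                 indicators = indicators),
            class = "hex_aggregates")
}

#' Apply the privacy floor to hex aggregates
#'
#' Returns only the cells whose participant count reaches the floor
#' `max(1, min_count)`; empty cells are never displayed, and cells below a
#' stricter configured floor are removed entirely (not zeroed). Non-empty
#' cells that fall below the floor are reported in the suppression summary
#' for audit.
#'
#' @param aggregates a [aggregate_bundle()] result.
#' @param min_count disclosure floor; the default 1 hides only empty cells.
#' @return object of class `hex_display`: the displayable subset of `cells`,
#'   `indicator_counts` and `tallies`, plus `suppression` (list with
#'   `hidden_cells`, `hidden_participants`, `min_count`).
#' @export
suppress_cells <- function(aggregates, min_count = 1) {
  stopifnot(inherits(aggregates, "hex_aggregates"))
  floor_n <- max(1, min_count)
  cells <- aggregates$cells
  keep <- cells$participant_count >= floor_n
  hidden <- cells$participant_count > 0 & !keep
  kept_keys <- .cell_key(cells$q[keep], cells$r[keep])
  ic <- aggregates$indicator_counts
  tl <- aggregates$tallies
  structure(list(
    grid = aggregates$grid,
    indicators = aggregates$indicators,
    cells = cells[keep, , drop = FALSE],
    indicator_counts = ic[.cell_key(ic$q, ic$r) %in% kept_keys, , drop = FALSE],
    tallies = tl[.cell_key(tl$q, tl$r) %in% kept_keys, , drop = FALSE],
    n_participants = aggregates$n_participants,
    suppression = list(hidden_cells = sum(hidden),
                       hidden_participants = sum(cells$participant_count[hidden]),
                       min_count = floor_n)
  ), class = "hex_display")
}

#' Serialize displayable hex cells to GeoJSON
#'
#' One polygon feature per displayable cell, with properties `cell_q`,
#' `cell_r`, `participant_count` and, per indicator, its numerator,
#' denominator and percentage value (`null` where the denominator is zero).
#' Vertices are unprojected back to lon/lat.
#'
#' @param display a [suppress_cells()] result.
#' @return GeoJSON FeatureCollection as a list (serialize with
#'   `jsonlite::toJSON(..., auto_unbox = TRUE)`).
#' @export
display_to_geojson <- function(display) {
  stopifnot(inherits(display, "hex_display"))
  grid <- display$grid
  kinds <- stats::setNames(
    vapply(display$indicators, function(d) d$kind, character(1)),
    vapply(display$indicators, function(d) d$name, character(1))
  )
  feats <- lapply(seq_len(nrow(display$cells)), function(i) {
    cell <- display$cells[i, ]
    verts <- hex_vertices(cell$cx, cell$cy, grid$circumradius, grid$orientation)
    ll <- unproject_planar(rbind(verts, verts[1, ]), grid$center)
    props <- list(cell_q = cell$q, cell_r = cell$r,
                  participant_count = cell$participant_count)
    ic <- display$indicator_counts
    rows <- ic[ic$q == cell$q & ic$r == cell$r, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      nm <- rows$indicator[j]
      props[[paste0(nm, "_numerator")]] <- rows$numerator[j]
      if (identical(unname(kinds[nm]), "ratio")) {
        props[[paste0(nm, "_denominator")]] <- rows$denominator[j]
        props[[paste0(nm, "_value")]] <-
          if (rows$denominator[j] > 0) {
            round(100 * rows$numerator[j] / rows$denominator[j], 2)
          } else NULL
      }
    }
    list(type = "Feature", properties = props,
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ll)),
                                     function(k) as.numeric(ll[k, ])))
         ))
  })
  list(type = "FeatureCollection", features = feats)
}
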