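# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the production code paths they check: assignment is brute-force
# nearest-center over all cells, overlap is convex polygon clipping, and
# counts are computed row by row.

# hand-built participant data.frame; cascade flags nest by construction
make_participants <- function(n, seed = 1, prevalence = 0.3,
                              p_diag = 0.9, p_art = 0.9, p_supp = 0.9,
                              lon_range = c(31.81, 31.99),
                              lat_range = c(-28.29, -28.11)) {
  set.seed(seed)
  hiv <- runif(n) < prevalence
  knows <- hiv & runif(n) < p_diag
  art <- knows & runif(n) < p_art
  supp <- art & runif(n) < p_supp
  data.frame(
    participant_id = sprintf("T%05d", seq_len(n)),
    lon = runif(n, lon_range[1], lon_range[2]),
    lat = runif(n, lat_range[1], lat_range[2]),
    hiv_positive = hiv, knows_status = knows, on_art = art,
    virally_suppressed = supp,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age_years = sample(0L:90L, n, replace = TRUE),
    education = sample(c("none", "primary", "secondary"), n, replace = TRUE),
    relationship_status = sample(c("single", "married"), n, replace = TRUE),
    employment = sample(c("employed", "unemployed"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

small_bundle <- function(n = 500, seed = 1, ...) {
  dataset_bundle(make_participants(n, seed, ...), default_region(),
                 as_of = as.Date("2026-01-01"))
}

# brute-force nearest-center assignment over every grid cell, with the
# same lexicographic tie-break the contract states
brute_assign <- function(grid, pts) {
  tol <- 1e-9 * grid$circumradius
  out <- matrix(NA_integer_, nrow(pts), 2)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((grid$cells$cx - pts[i, 1])^2 + (grid$cells$cy - pts[i, 2])^2)
    cand <- which(d <= min(d) + tol)
    cand <- cand[order(grid$cells$q[cand], grid$cells$r[cand])]
    out[i, ] <- c(grid$cells$q[cand[1]], grid$cells$r[cand[1]])
  }
  out
}

# Sutherland-Hodgman clip of convex CCW rings; returns intersection area
convex_clip_area <- function(subject, clip) {
  poly <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(poly) || nrow(poly) < 3) return(0)
    a <- clip[i, ]
    b <- clip[if (i == n) 1 else i + 1, ]
    side <- (b[1] - a[1]) * (poly[, 2] - a[2]) -
      (b[2] - a[2]) * (poly[, 1] - a[1])
    m <- nrow(poly)
    out <- list()
    for (j in seq_len(m)) {
      k <- if (j == m) 1 else j + 1
      if (side[j] >= 0) out[[length(out) + 1]] <- poly[j, ]
      if ((side[j] > 0 && side[k] < 0) || (side[j] < 0 && side[k] > 0)) {
        t <- side[j] / (side[j] - side[k])
        out[[length(out) + 1]] <- poly[j, ] + t * (poly[k, ] - poly[j, ])
      }
    }
    poly <- if (length(out) > 0) do.call(rbind, out) else NULL
  }
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  abs(sum(x * y[j] - x[j] * y) / 2)
}

write_temp_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a dashboard folder with a small synthetic population, for shell tests
make_dashboard_folder <- function(root, name = "tasp", n = 800, seed = 11,
                                  circumradius = 1500) {
  d <- file.path(root, name)
  synth_dashboard_folder(
    d, synth_params(n_participants = n, seed = seed),
    grid = list(circumradius_m = circumradius, orientation = "flat_top",
                min_count = 1)
  )
  d
}
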