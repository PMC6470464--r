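# Synthetic TasP-like HDSS populations: spatially clustered homesteads
# inside a region polygon, a young-skewed age/sex structure, age- and
# sex-dependent HIV prevalence, and cascade stages drawn sequentially so
# the nesting (suppressed within on-ART within diagnosed within positive)
# holds by construction. One seed governs every draw, so bundles are
# bit-reproducible fixtures.

#' Built-in default study region
#'
#' A square region of the given side length centered on rural
#' KwaZulu-Natal coordinates, the kind of HDSS catchment the framework
#' targets. Includes a small synthetic "clinics" point layer.
#'
#' @param side_km side length in kilometers.
#' @param center lon/lat center.
#' @return a [study_region()].
#' @export
default_region <- function(side_km = 20, center = c(31.90, -28.20)) {
  h <- side_km * 1000 / 2
  corners <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
  ll <- unproject_planar(corners, center)
  clinics <- unproject_planar(rbind(c(-h / 2, 0), c(h / 3, h / 3)), center)
  study_region(ll, layers = list(clinics = list(type = "point",
                                                coords = clinics)))
}

# default HIV prevalence by age band and sex: negligible in children,
# peaking in mid-adulthood, higher among women — the age/sex pattern of a
# severe generalized epidemic
.default_prevalence <- data.frame(
  age_lo = c(0, 15, 25, 35, 45, 55),
  age_hi = c(14, 24, 34, 44, 54, Inf),
  female = c(0.02, 0.12, 0.35, 0.40, 0.30, 0.15),
  male   = c(0.02, 0.05, 0.20, 0.30, 0.25, 0.12)
)

# young-skewed age pyramid over 5-year bins 0-4 ... 85+
.default_age_probs <- local({
  w <- c(14, 13, 12, 11, 9, 8, 7, 6, 5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.75, 0.75)
  w / sum(w)
})

.default_categoricals <- list(
  education = c(none = 0.15, primary = 0.30, secondary = 0.40,
                tertiary = 0.10, unknown = 0.05),
  relationship_status = c(single = 0.40, married = 0.25, partnered = 0.20,
                          widowed = 0.10, unknown = 0.05),
  employment = c(employed = 0.30, unemployed = 0.45, student = 0.15,
                 retired = 0.05, unknown = 0.05)
)

#' Parameters for the synthetic population generator
#'
#' Defaults describe the emulated trial conditions: 10,000 participants in
#' clustered homesteads, a severe generalized HIV epidemic, and cascade
#' progression probabilities of 0.9 at each stage (the 90/90/90 targets
#' exactly met in expectation).
#'
#' @param n_participants number of records to generate.
#' @param region a [study_region()]; defaults to [default_region()].
#' @param n_clusters number of homestead clusters (>= 1).
#' @param cluster_spread within-cluster standard deviation, meters.
#' @param prevalence_by_age_sex data.frame with columns `age_lo`, `age_hi`,
#'   `female`, `male` giving P(HIV-positive | age band, sex).
#' @param p_diagnosed P(knows status | positive).
#' @param p_art P(on ART | diagnosed).
#' @param p_suppressed P(suppressed | on ART).
#' @param age_probs probabilities over the 18 five-year age bins 0-4 ... 85+.
#' @param categorical_distributions named list of label-probability vectors
#'   for `education`, `relationship_status`, `employment`; each sums to 1.
#' @param seed integer governing all draws.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(n_participants = 10000,
                         region = default_region(),
                         n_clusters = 12,
                         cluster_spread = 800,
                         prevalence_by_age_sex = .default_prevalence,
                         p_diagnosed = 0.9, p_art = 0.9, p_suppressed = 0.9,
                         age_probs = .default_age_probs,
                         categorical_distributions = .default_categoricals,
                         seed = 1) {
  probs <- c(p_diagnosed, p_art, p_suppressed,
             prevalence_by_age_sex$female, prevalence_by_age_sex$male)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  for (nm in names(categorical_distributions)) {
    if (abs(sum(categorical_distributions[[nm]]) - 1) > 1e-8) {
      stop("categorical distribution '", nm, "' must sum to 1")
    }
  }
  stopifnot(length(age_probs) == 18, abs(sum(age_probs) - 1) < 1e-8)
  structure(list(n_participants = n_participants, region = region,
                 n_clusters = n_clusters, cluster_spread = cluster_spread,
                 prevalence_by_age_sex = prevalence_by_age_sex,
                 p_diagnosed = p_diagnosed, p_art = p_art,
                 p_suppressed = p_suppressed, age_probs = age_probs,
                 categorical_distributions = categorical_distributions,
                 seed = seed),
            class = "synth_params")
}

#' Generate a synthetic dataset bundle
#'
#' Locations are a mixture of isotropic Gaussian scatters around cluster
#' centers drawn uniformly inside the region (rejection-sampled to the
#' polygon), mimicking homestead settlement clustering. Cascade flags are
#' drawn sequentially, so nesting holds by construction. Deterministic
#' given the seed.
#'
#' @param params a [synth_params()].
#' @return a [dataset_bundle()] with `n_participants` records; `as_of` is
#'   fixed (not wall-clock) so equal seeds give identical bundles.
#' @export
synth_generate <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  region <- params$region
  n <- params$n_participants
  bnd <- project_planar(region$boundary, region$center)
  xmin <- min(bnd[, 1]); xmax <- max(bnd[, 1])
  ymin <- min(bnd[, 2]); ymax <- max(bnd[, 2])

  draw_in_polygon <- function(k, proposal) {
    out <- matrix(NA_real_, k, 2)
    need <- seq_len(k)
    attempts <- 0
    while (length(need) > 0) {
      cand <- proposal(length(need))
      inside <- points_in_polygon(bnd, cand)
      out[need[inside], ] <- cand[inside, , drop = FALSE]
      need <- need[!inside]
      attempts <- attempts + 1
      if (attempts > 200) {
        stop("generation error: rejection rate above 99%; the region is ",
             "too small for the requested cluster_spread")
      }
    }
    out
  }

  centers <- draw_in_polygon(params$n_clusters, function(m) {
    cbind(stats::runif(m, xmin, xmax), stats::runif(m, ymin, ymax))
  })
  cl <- sample.int(params$n_clusters, n, replace = TRUE)
  xy <- matrix(NA_real_, n, 2)
  for (c_i in seq_len(params$n_clusters)) {
    idx <- which(cl == c_i)
    if (length(idx) == 0) next
    xy[idx, ] <- draw_in_polygon(length(idx), function(m) {
      cbind(stats::rnorm(m, centers[c_i, 1], params$cluster_spread),
            stats::rnorm(m, centers[c_i, 2], params$cluster_spread))
    })
  }
  ll <- unproject_planar(xy, region$center)

  bin <- sample.int(18, n, replace = TRUE, prob = params$age_probs)
  age_lo <- (bin - 1) * 5
  width <- ifelse(bin == 18, 15, 5)  # 85+ spans 85-99
  age <- age_lo + floor(stats::runif(n) * width)
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")

  prev <- params$prevalence_by_age_sex
  band <- findInterval(age, prev$age_lo)
  p_hiv <- ifelse(sex == "female", prev$female[band], prev$male[band])
  hiv <- stats::runif(n) < p_hiv
  knows <- hiv & stats::runif(n) < params$p_diagnosed
  art <- knows & stats::runif(n) < params$p_art
  supp <- art & stats::runif(n) < params$p_suppressed

  draw_cat <- function(dist) {
    names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
  }
  cd <- params$categorical_distributions

  participants <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    lon = ll[, 1], lat = ll[, 2],
    hiv_positive = hiv, knows_status = knows, on_art = art,
    virally_suppressed = supp,
    sex = sex, age_years = as.integer(age),
    education = draw_cat(cd$education),
    relationship_status = draw_cat(cd$relationship_status),
    employment = draw_cat(cd$employment),
    stringsAsFactors = FALSE
  )
  bundle <- dataset_bundle(participants, region, as_of = as.Date("2026-01-01"))
  # drawn cluster centers (planar meters), kept for diagnostics and tests
  attr(bundle, "cluster_centers") <- centers
  bundle
}

#' Emit a complete ready-to-serve dashboard folder
#'
#' Writes the synthetic bundle's data files plus a dashboard config into
#' `directory`, so that [discover_dashboards()] on the parent immediately
#' picks it up.
#'
#' @param directory target folder (created if needed).
#' @param params a [synth_params()].
#' @param title dashboard title.
#' @param grid list of grid settings (`circumradius_m`, `orientation`,
#'   `min_count`); circumradius `"auto"` sizes the grid to yield on the
#'   order of a few hundred populated cells.
#' @param classification list with `method`, `n_classes`.
#' @return the config path, invisibly.
#' @export
synth_dashboard_folder <- function(directory, params = synth_params(),
                                   title = "Synthetic TasP trial",
                                   grid = list(circumradius_m = "auto",
                                               orientation = "flat_top",
                                               min_count = 1),
                                   classification = list(method = "quantile",
                                                         n_classes = 5)) {
  bundle <- synth_generate(params)
  write_bundle(bundle, directory)
  config <- list(
    title = title,
    data = list(participants = "participants.csv", region = "region.geojson"),
    grid = grid,
    indicators = names(cascade_indicators()),
    chart_menu = analysis_chart_names,
    classification = classification,
    targets = list(diagnosed_of_positive = 90, art_of_diagnosed = 90,
                   suppressed_of_art = 90)
  )
  cfg_path <- file.path(directory, "dashboard.yml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
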