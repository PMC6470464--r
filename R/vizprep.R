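# Renderer-agnostic chart payloads for the overview and analysis pages.
# Payloads end at structured data plus class indices; color palettes and
# rendering belong to the (thin) client. Ratios are rounded to two decimal
# places at this serialization boundary, full precision is kept upstream.

#' Default age bins
#'
#' Five-year bins 0-4 ... 85+ for the population pyramid; ten-year bins
#' 0-9 ... 80+ for the HIV-by-age stacked chart (wider bins limit sparse
#' cells at hex scale).
#' @name age_bins
NULL

.pyramid_breaks <- c(seq(0, 85, 5), Inf)
.pyramid_labels <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
.stacked_breaks <- c(seq(0, 80, 10), Inf)
.stacked_labels <- c(paste(seq(0, 70, 10), seq(9, 79, 10), sep = "-"), "80+")

.bin_ages <- function(age, breaks, labels) {
  cut(age, breaks = breaks, labels = labels, right = FALSE)
}

.round2 <- function(x) ifelse(is.na(x), NA_real_, round(x, 2))

#' Classify per-cell values into choropleth classes
#'
#' Quantile classification balances class occupancy (counts differ by at
#' most one for distinct values); equal-interval divides the value range
#' evenly. Cells with undefined values (NA) are excluded and flagged, not
#' classified. An all-equal input collapses to a single class and is
#' flagged as degenerate rather than raising an error.
#'
#' @param values numeric vector of per-cell indicator values (may contain
#'   NA for undefined ratios).
#' @param n_classes number of classes (>= 2).
#' @param method `"quantile"` (default) or `"equal_interval"`.
#' @param cell_keys optional data.frame with columns `q`, `r` aligned with
#'   `values`; carried through to the per-cell class map.
#' @return object of class `choropleth_layer`: `method`, `n_classes`
#'   (effective), `breaks` (full ascending break vector, endpoints
#'   included), `classes` (integer class index per input, NA for excluded),
#'   `cell_classes` (data.frame q, r, class when `cell_keys` given),
#'   `excluded` (indices of NA inputs), `degenerate` flag.
#' @export
classify_values <- function(values, n_classes = 5,
                            method = c("quantile", "equal_interval"),
                            cell_keys = NULL) {
  method <- match.arg(method)
  if (n_classes < 2) stop("n_classes must be >= 2")
  defined <- !is.na(values)
  if (!any(defined)) stop("classification needs at least one defined value")
  v <- values[defined]
  degenerate <- FALSE
  if (length(unique(v)) == 1) {
    breaks <- c(v[1], v[1])
    classes <- ifelse(defined, 1L, NA_integer_)
    degenerate <- TRUE
    n_eff <- 1L
  } else {
    breaks <- if (method == "quantile") {
      stats::quantile(v, probs = seq(0, 1, length.out = n_classes + 1),
                      type = 7, names = FALSE)
    } else {
      seq(min(v), max(v), length.out = n_classes + 1)
    }
    breaks <- unique(breaks)
    if (length(breaks) < n_classes + 1) degenerate <- TRUE  # ties collapsed classes
    n_eff <- length(breaks) - 1L
    cls <- cut(v, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    classes <- rep(NA_integer_, length(values))
    classes[defined] <- as.integer(cls)
  }
  cell_classes <- NULL
  if (!is.null(cell_keys)) {
    cell_classes <- data.frame(q = cell_keys$q[defined],
                               r = cell_keys$r[defined],
                               class = classes[defined])
  }
  structure(list(method = method, n_classes = n_eff, breaks = breaks,
                 classes = classes, cell_classes = cell_classes,
                 excluded = which(!defined), degenerate = degenerate),
            class = "choropleth_layer")
}

# per-cell indicator values reconstructed from aggregated counts; returns
# indicator_value objects so cell and global scopes share one shape
cell_cascade_values <- function(display, spec, cell) {
  ic <- display$indicator_counts
  rows <- ic[ic$q == cell[1] & ic$r == cell[2], , drop = FALSE]
  lapply(spec, function(defn) {
    row <- rows[rows$indicator == defn$name, , drop = FALSE]
    num <- row$numerator[1]
    den <- row$denominator[1]
    if (defn$kind == "number") {
      structure(list(indicator = defn$name, scope = c(cell[1], cell[2]),
                     numerator = num, denominator = NA_integer_, value = num,
                     undefined_reason = NULL, target = defn$target),
                class = "indicator_value")
    } else {
      structure(list(indicator = defn$name, scope = c(cell[1], cell[2]),
                     numerator = num, denominator = den,
                     value = if (den > 0) 100 * num / den else NA_real_,
                     undefined_reason = if (den == 0) "denominator is zero",
                     target = defn$target),
                class = "indicator_value")
      }
  })
}

#' Donut chart payload for one indicator value
#'
#' @param value an `indicator_value`.
#' @return list: `indicator`, `percentage` (2 dp; NA when undefined, with
#'   `undefined_reason`), `center_label`, `target` (target ring percentage
#'   or NULL).
#' @export
donut_payload <- function(value) {
  if (value$indicator == "trial_participants" ||
      (!is.null(value$denominator) && is.na(value$denominator))) {
    return(list(chart = "donut", indicator = value$indicator,
                percentage = NULL, count = value$numerator,
                center_label = format(value$numerator, big.mark = ","),
                target = value$target))
  }
  pct <- .round2(value$value)
  list(chart = "donut", indicator = value$indicator,
       percentage = if (is.na(pct)) NULL else pct,
       center_label = if (is.na(pct)) "n/a" else sprintf("%.2f%%", pct),
       undefined_reason = value$undefined_reason,
       target = value$target)
}

#' Horizontal bar payload comparing local and global indicator values
#'
#' @param comparison output of [compare_local_global()].
#' @return list with `orientation = "horizontal"` and `rows` in cascade
#'   order, each `(indicator, local, global, difference, target)`.
#' @export
bar_comparison_payload <- function(comparison) {
  rows <- lapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    list(indicator = r$indicator,
         local = if (is.na(r$local)) NULL else .round2(r$local),
         global = if (is.na(r$global)) NULL else .round2(r$global),
         difference = if (is.na(r$difference)) NULL else .round2(r$difference),
         target = if (is.na(r$target)) NULL else r$target)
  })
  list(chart = "bar_comparison", orientation = "horizontal", rows = rows)
}

#' Population pyramid payload
#'
#' @param participants base population (already filtered to the cell and,
#'   when requested, to an indicator population).
#' @return list: ordered `age_bins`, `female_counts`, `male_counts`,
#'   `base_size` (== sum of both count vectors).
#' @export
pyramid_payload <- function(participants) {
  bin <- .bin_ages(participants$age_years, .pyramid_breaks, .pyramid_labels)
  tab <- table(bin, factor(participants$sex, levels = c("female", "male")))
  list(chart = "pyramid", age_bins = .pyramid_labels,
       female_counts = as.integer(tab[, "female"]),
       male_counts = as.integer(tab[, "male"]),
       base_size = nrow(participants))
}

#' Normalized stacked-bar payload: HIV status fraction by age group
#'
#' @param participants base population.
#' @return list: `age_bins`, `positive_fraction` and `negative_fraction`
#'   per bin (each pair sums to 1 for nonempty bins, NA for empty bins),
#'   `bin_sizes`.
#' @export
stacked_bar_payload <- function(participants) {
  bin <- .bin_ages(participants$age_years, .stacked_breaks, .stacked_labels)
  n_bin <- as.integer(table(bin))
  pos <- as.integer(table(bin[participants$hiv_positive]))
  frac <- ifelse(n_bin > 0, pos / n_bin, NA_real_)
  list(chart = "stacked_bar", variable = "hiv_positive",
       age_bins = .stacked_labels,
       positive_fraction = .round2(frac),
       negative_fraction = .round2(ifelse(is.na(frac), NA_real_, 1 - frac)),
       bin_sizes = n_bin)
}

#' Treemap payload for a categorical variable
#'
#' Tiles are ordered by descending count, ties broken alphabetically, so
#' the layout input is deterministic.
#'
#' @param participants base population for `total_population` mode.
#' @param variable categorical field name.
#' @param mode normalization mode (see [normalize_breakdown()]).
#' @param indicator indicator whose numerator set defines the base in
#'   `indicator_population` mode.
#' @return list: `variable`, `base` (mode), `base_size`, `tiles` (ordered
#'   list of `(label, count, proportion)`), `undefined` flag for an empty
#'   base.
#' @export
treemap_payload <- function(participants, variable,
                            mode = "total_population", indicator = NULL) {
  bd <- normalize_breakdown(participants, variable, mode, indicator)
  ord <- if (length(bd$counts) > 0) order(-bd$counts, names(bd$counts))
         else integer(0)
  tiles <- lapply(ord, function(i) {
    list(label = names(bd$counts)[i], count = bd$counts[[i]],
         proportion = round(unname(bd$proportions[i]), 4))
  })
  list(chart = "treemap", variable = variable, base = bd$mode,
       base_size = bd$base_size, tiles = tiles, undefined = bd$undefined)
}

# pie and plain bar charts share the treemap's breakdown machinery
.breakdown_payload <- function(chart, participants, variable, mode, indicator) {
  out <- treemap_payload(participants, variable, mode, indicator)
  out$chart <- chart
  names(out)[names(out) == "tiles"] <- "slices"
  out
}

#' Scatter payload over displayable cells
#'
#' Each point is one displayable hex cell, positioned by a pair of
#' indicator values — the cell is the unit of analysis, so no participant
#'-level data appears. Cells where either value is undefined are dropped.
#'
#' @param display a [suppress_cells()] result.
#' @param spec cascade spec (named list of definitions).
#' @param x_indicator,y_indicator indicator names.
#' @return list with `points`: `(cell_q, cell_r, x, y)` per retained cell.
#' @export
scatter_payload <- function(display, spec, x_indicator, y_indicator) {
  pts <- lapply(seq_len(nrow(display$cells)), function(i) {
    cell <- c(display$cells$q[i], display$cells$r[i])
    vals <- cell_cascade_values(display, spec, cell)
    nm <- vapply(vals, function(v) v$indicator, character(1))
    vx <- vals[[match(x_indicator, nm)]]$value
    vy <- vals[[match(y_indicator, nm)]]$value
    if (is.na(vx) || is.na(vy)) return(NULL)
    list(cell_q = display$cells$q[i], cell_r = display$cells$r[i],
         x = .round2(vx), y = .round2(vy))
  })
  list(chart = "scatter", x_indicator = x_indicator,
       y_indicator = y_indicator, points = Filter(Negate(is.null), pts))
}

#' Valid analysis-page chart names
#' @export
analysis_chart_names <- c("pyramid", "hiv_by_age", "treemap_education",
                          "treemap_relationship", "treemap_employment",
                          "pie", "bar", "scatter")

#' Build the overview page payload
#'
#' Assembles the three display areas of the overview page: the choropleth
#' map layer for the active indicator (with embedded hex GeoJSON), the
#' global KPI donuts, and — when a hex is selected — the footer comparing
#' local to global indicator performance plus the number of participants
#' residing in the cell. Only displayable (post-suppression) cells can be
#' selected.
#'
#' @param display a [suppress_cells()] result.
#' @param global_values global cascade values ([compute_cascade()]).
#' @param spec cascade spec used for both.
#' @param active_indicator indicator shown on the map.
#' @param selected_cell optional `c(q, r)`.
#' @param classification list with `method` and `n_classes`.
#' @param data_version content hash carried into the envelope.
#' @param generated_at timestamp string recorded in the envelope; pass the
#'   instance's refresh time so identical state yields identical payloads.
#' @return payload envelope list (see [payload_json()]).
#' @export
build_overview_payload <- function(display, global_values, spec,
                                   active_indicator = "hiv_prevalence",
                                   selected_cell = NULL,
                                   classification = list(method = "quantile",
                                                         n_classes = 5),
                                   data_version = "unversioned",
                                   generated_at = "") {
  stopifnot(inherits(display, "hex_display"))
  nm <- vapply(spec, function(d) d$name, character(1))
  if (!active_indicator %in% nm) {
    stop("unknown indicator: ", active_indicator)
  }
  defn <- spec[[match(active_indicator, nm)]]
  ic <- display$indicator_counts
  rows <- ic[ic$indicator == active_indicator, , drop = FALSE]
  ord <- match(.cell_key(display$cells$q, display$cells$r),
               .cell_key(rows$q, rows$r))
  rows <- rows[ord, , drop = FALSE]
  vals <- if (defn$kind == "number") {
    as.numeric(rows$numerator)
  } else {
    ifelse(rows$denominator > 0, 100 * rows$numerator / rows$denominator,
           NA_real_)
  }
  layer <- classify_values(vals, n_classes = classification$n_classes,
                           method = classification$method,
                           cell_keys = display$cells)
  choropleth <- list(
    type = "choropleth", indicator = active_indicator,
    method = layer$method, n_classes = layer$n_classes,
    breaks = .round2(as.numeric(layer$breaks)),
    degenerate = layer$degenerate,
    cells = lapply(seq_len(nrow(layer$cell_classes)), function(i) {
      list(cell_q = layer$cell_classes$q[i], cell_r = layer$cell_classes$r[i],
           class = layer$cell_classes$class[i])
    }),
    undefined_cells = length(layer$excluded),
    geojson = display_to_geojson(display),
    suppression = display$suppression
  )
  donuts <- list(type = "donuts",
                 charts = lapply(global_values, donut_payload))
  sections <- list(choropleth, donuts)
  if (!is.null(selected_cell)) {
    keys <- .cell_key(display$cells$q, display$cells$r)
    sel <- .cell_key(selected_cell[1], selected_cell[2])
    if (!sel %in% keys) {
      stop("selection error: cell (", selected_cell[1], ", ",
           selected_cell[2], ") is not displayable")
    }
    cv <- cell_cascade_values(display, spec, selected_cell)
    footer <- list(
      type = "footer_comparison",
      cell_q = selected_cell[1], cell_r = selected_cell[2],
      participant_count =
        display$cells$participant_count[keys == sel],
      comparison = bar_comparison_payload(
        compare_local_global(spec, cv, global_values)),
      info = lapply(spec, function(d) {
        list(indicator = d$name, info_text = d$info_text)
      })
    )
    sections <- c(sections, list(footer))
  }
  payload_envelope("overview", sections, data_version, generated_at)
}

#' Build the analysis page payload for one hex cell
#'
#' Assembles the four display areas of the analysis page: the requested
#' explanatory charts over the cell's residents, the local-vs-global KPI
#' comparison bars, the control sidebar (mini-map marker plus global
#' categorical breakdowns), and the key-numbers footer (gender breakdown,
#' prevalence, KPIs). Chart bases honor the normalization mode: total cell
#' population or the population matching an indicator.
#'
#' @param display a [suppress_cells()] result (the cell must be displayable).
#' @param aggregates the [aggregate_bundle()] result (provides the
#'   participant-to-cell assignment; never serialized).
#' @param bundle the [dataset_bundle()].
#' @param cell `c(q, r)` of the selected hex.
#' @param spec cascade spec.
#' @param chart_menu character vector of requested charts (subset of
#'   [analysis_chart_names]).
#' @param normalization `"total_population"` or `"indicator_population"`.
#' @param indicator_filter indicator name defining the base in
#'   `indicator_population` mode.
#' @param scatter_indicators length-2 indicator names for the scatter chart.
#' @param data_version,generated_at envelope metadata.
#' @return payload envelope list.
#' @export
build_analysis_payload <- function(display, aggregates, bundle, cell, spec,
                                   chart_menu = c("pyramid", "hiv_by_age",
                                                  "treemap_education"),
                                   normalization = "total_population",
                                   indicator_filter = NULL,
                                   scatter_indicators =
                                     c("hiv_prevalence", "art_of_diagnosed"),
                                   data_version = "unversioned",
                                   generated_at = "") {
  stopifnot(inherits(display, "hex_display"))
  bad <- setdiff(chart_menu, analysis_chart_names)
  if (length(bad) > 0) {
    stop("menu error: unknown chart(s) ", paste(bad, collapse = ", "),
         "; valid charts are: ", paste(analysis_chart_names, collapse = ", "))
  }
  keys <- .cell_key(display$cells$q, display$cells$r)
  sel <- .cell_key(cell[1], cell[2])
  if (!sel %in% keys) {
    stop("selection error: cell (", cell[1], ", ", cell[2],
         ") is not displayable")
  }
  nm <- vapply(spec, function(d) d$name, character(1))
  asg <- aggregates$assignment
  in_cell <- asg$point[asg$q == cell[1] & asg$r == cell[2]]
  cell_p <- bundle$participants[in_cell, , drop = FALSE]

  filt_defn <- NULL
  base_p <- cell_p
  if (identical(normalization, "indicator_population")) {
    if (is.null(indicator_filter) || !indicator_filter %in% nm) {
      stop("indicator_population mode needs a valid indicator_filter")
    }
    filt_defn <- spec[[match(indicator_filter, nm)]]
    base_p <- cell_p[indicator_numerator(filt_defn, cell_p), , drop = FALSE]
  }

  one_chart <- function(chart) {
    switch(chart,
      pyramid = pyramid_payload(base_p),
      hiv_by_age = stacked_bar_payload(base_p),
      treemap_education = treemap_payload(cell_p, "education",
                                          normalization, filt_defn),
      treemap_relationship = treemap_payload(cell_p, "relationship_status",
                                             normalization, filt_defn),
      treemap_employment = treemap_payload(cell_p, "employment",
                                           normalization, filt_defn),
      pie = .breakdown_payload("pie", cell_p, "sex", normalization, filt_defn),
      bar = .breakdown_payload("bar", cell_p, "education", normalization,
                               filt_defn),
      scatter = scatter_payload(display, spec, scatter_indicators[1],
                                scatter_indicators[2])
    )
  }
  explanatory <- list(type = "explanatory_charts",
                      normalization = normalization,
                      indicator_filter = indicator_filter,
                      charts = lapply(chart_menu, one_chart))

  cv <- cell_cascade_values(display, spec, cell)
  gv <- compute_cascade(spec, bundle$participants, scope = "global")
  comparison <- list(type = "local_global_comparison",
                     comparison = bar_comparison_payload(
                       compare_local_global(spec, cv, gv)))

  centroid_ll <- unproject_planar(
    as.matrix(display$cells[keys == sel, c("cx", "cy")]),
    display$grid$center)
  control <- list(
    type = "control_sidebar",
    minimap = list(cell_q = cell[1], cell_r = cell[2],
                   centroid_lon = round(centroid_ll[1, 1], 4),
                   centroid_lat = round(centroid_ll[1, 2], 4)),
    available_charts = as.list(analysis_chart_names),
    global_breakdowns = lapply(c("education", "relationship_status",
                                 "employment"), function(v) {
      bd <- normalize_breakdown(bundle$participants, v, "total_population")
      list(variable = v,
           labels = as.list(names(bd$counts)),
           proportions = as.list(round(unname(bd$proportions), 4)))
    })
  )

  sex_tab <- table(factor(cell_p$sex, levels = c("female", "male")))
  kpis <- lapply(cv, function(v) {
    list(indicator = v$indicator,
         value = if (is.na(v$value)) NULL else .round2(v$value))
  })
  key_numbers <- list(type = "key_numbers",
                      participant_count = nrow(cell_p),
                      female = as.integer(sex_tab["female"]),
                      male = as.integer(sex_tab["male"]),
                      kpis = kpis)

  payload_envelope("analysis", list(explanatory, comparison, control,
                                    key_numbers),
                   data_version, generated_at,
                   extra = list(cell_q = cell[1], cell_r = cell[2]))
}

#' Payload envelope
#'
#' All pages serialize to the same JSON envelope:
#' `{page, sections[], generated_at, data_version}`.
#'
#' @param page `"overview"` or `"analysis"`.
#' @param sections list of section lists, each with a `type`.
#' @param data_version content hash of the instance's data files.
#' @param generated_at timestamp string; use the instance refresh time so
#'   identical state serializes identically.
#' @param extra optional named list merged into the envelope top level.
#' @return envelope list.
#' @export
payload_envelope <- function(page, sections, data_version, generated_at,
                             extra = NULL) {
  env <- list(page = page, sections = sections,
              generated_at = generated_at, data_version = data_version)
  if (!is.null(extra)) env <- c(env, extra)
  env
}

#' Serialize a payload envelope to its canonical JSON text
#'
#' @param payload an envelope list.
#' @return length-1 character, the JSON document.
#' @export
payload_json <- function(payload) {
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}
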