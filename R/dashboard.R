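# The framework shell: a dashboard is a folder holding a declarative config
# (dashboard.yml) plus the standard data files. Dropping a new folder under
# the served root creates a new dashboard; refresh re-runs the full pipeline
# only when file content actually changed, and a refresh that fails
# validation keeps the previous materialized state serving.

#' Read and validate a dashboard folder's config
#'
#' The config is a single YAML file `dashboard.yml` at the folder root,
#' declaring the data files, grid parameters, indicator list, chart menu,
#' classification and per-indicator targets. Validation checks that the
#' referenced data files exist, indicator names resolve against the
#' catalog (or are well-formed custom definitions) and chart names are
#' valid.
#'
#' @param folder dashboard folder path.
#' @return object of class `dashboard_config`.
#' @export
read_dashboard_config <- function(folder) {
  cfg_path <- file.path(folder, "dashboard.yml")
  if (!file.exists(cfg_path)) {
    stop("no dashboard.yml in ", folder)
  }
  raw <- yaml::read_yaml(cfg_path)
  if (is.null(raw$title)) stop("config error: missing title")
  if (is.null(raw$data$participants) || is.null(raw$data$region)) {
    stop("config error: data.participants and data.region are required")
  }
  pp <- file.path(folder, raw$data$participants)
  rp <- file.path(folder, raw$data$region)
  for (f in c(pp, rp)) {
    if (!file.exists(f)) stop("config error: data file not found: ", f)
  }
  grid <- raw$grid
  if (is.null(grid)) grid <- list()
  if (is.null(grid$circumradius_m)) grid$circumradius_m <- "auto"
  if (is.null(grid$orientation)) grid$orientation <- "flat_top"
  if (!grid$orientation %in% c("flat_top", "pointy_top")) {
    stop("config error: unknown orientation ", grid$orientation)
  }
  if (is.null(grid$min_count)) grid$min_count <- 1
  cls <- raw$classification
  if (is.null(cls)) cls <- list()
  if (is.null(cls$method)) cls$method <- "quantile"
  if (!cls$method %in% c("quantile", "equal_interval")) {
    stop("config error: unknown classification method ", cls$method)
  }
  if (is.null(cls$n_classes)) cls$n_classes <- 5

  targets <- raw$targets
  if (is.null(targets)) {
    targets <- list(diagnosed_of_positive = 90, art_of_diagnosed = 90,
                    suppressed_of_art = 90)
  }
  spec <- .resolve_indicators(raw$indicators, targets)

  menu <- raw$chart_menu
  if (is.null(menu)) menu <- analysis_chart_names
  menu <- unlist(menu)
  bad <- setdiff(menu, analysis_chart_names)
  if (length(bad) > 0) {
    stop("config error: unknown chart(s) ", paste(bad, collapse = ", "))
  }

  structure(list(title = raw$title, folder = normalizePath(folder),
                 participants_path = pp, region_path = rp, grid = grid,
                 spec = spec, chart_menu = menu, classification = cls),
            class = "dashboard_config")
}

.resolve_indicators <- function(entries, targets) {
  catalog <- cascade_indicators(targets = unlist(targets))
  if (is.null(entries)) return(catalog)
  defs <- list()
  for (e in entries) {
    if (is.character(e) && length(e) == 1) {
      if (!e %in% names(catalog)) {
        stop("config error: unknown indicator '", e, "'")
      }
      defs[[e]] <- catalog[[e]]
    } else if (is.list(e) && !is.null(e$name)) {
      defs[[e$name]] <- custom_indicator(e$name, e)
    } else {
      stop("config error: indicator entries must be catalog names or ",
           "custom definitions with a name")
    }
  }
  defs
}

.data_version <- function(config) {
  md5 <- tools::md5sum(c(config$participants_path, config$region_path))
  paste(unname(md5), collapse = ":")
}

# grid auto-sizing: aim for a few hundred populated cells (150-400 when the
# data admit it); bounded fixed-point iteration on the cell radius
.auto_circumradius <- function(bundle, orientation, target = 250,
                               lo = 150, hi = 400) {
  region <- bundle$region
  bnd <- project_planar(region$boundary, region$center)
  bbox_area <- diff(range(bnd[, 1])) * diff(range(bnd[, 2]))
  R <- sqrt(bbox_area / (target * 3 * sqrt(3) / 2))
  best <- NULL
  for (i in 1:8) {
    grid <- build_grid(region, R, orientation)
    xy <- project_planar(cbind(bundle$participants$lon,
                               bundle$participants$lat), region$center)
    asg <- assign_points(grid, xy)
    pop <- nrow(unique(asg[, c("q", "r")]))
    if (is.null(best) || abs(pop - target) < abs(best$pop - target)) {
      best <- list(R = R, pop = pop)
    }
    if (pop >= lo && pop <= hi) return(R)
    if (pop == 0) break
    R <- R * sqrt(pop / target)
    short <- min(diff(range(bnd[, 1])), diff(range(bnd[, 2])))
    R <- min(R, short * 0.9)
  }
  best$R
}

#' Materialize a dashboard instance from its config
#'
#' Runs the full pipeline — load, validate, grid, aggregate, suppress,
#' global cascade — and captures a content hash (`data_version`) of the
#' data files. Load or validation failure raises an error (callers such as
#' [refresh_dashboard()] keep the previous state in that case).
#'
#' @param config a [read_dashboard_config()] result.
#' @return object of class `dashboard_instance`.
#' @export
materialize_dashboard <- function(config) {
  stopifnot(inherits(config, "dashboard_config"))
  loaded <- load_participants(config$participants_path)
  if (nrow(loaded$rejected) > 0) {
    stop("validation failure: ", nrow(loaded$rejected),
         " participant row(s) rejected; first reason: ",
         loaded$rejected$reason[1])
  }
  region <- load_region(config$region_path)
  bundle <- dataset_bundle(loaded$records, region)
  report <- validate_bundle(bundle)
  if (nrow(report) > 0) {
    stop("validation failure: ", nrow(report), " issue(s); first: ",
         report$type[1], " (", report$participant_id[1], ")")
  }
  R <- config$grid$circumradius_m
  if (identical(R, "auto")) {
    R <- .auto_circumradius(bundle, config$grid$orientation)
  }
  grid <- build_grid(region, R, config$grid$orientation)
  aggregates <- aggregate_bundle(grid, bundle, config$spec)
  display <- suppress_cells(aggregates, config$grid$min_count)
  global_values <- compute_cascade(config$spec, bundle$participants, "global")
  dv <- .data_version(config)
  structure(list(config = config, bundle = bundle, grid = grid,
                 aggregates = aggregates, display = display,
                 global_values = global_values, data_version = dv,
                 last_refresh = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 status = list(ok = TRUE, last_error = NULL)),
            class = "dashboard_instance")
}

#' Discover dashboard folders under a root
#'
#' One descriptor per subfolder containing a valid config; folders whose
#' config fails to read or validate are reported as diagnostics, never
#' fatal — a broken dashboard cannot affect its siblings.
#'
#' @param root directory holding dashboard folders.
#' @return list with `instances` (named list of `dashboard_config`s) and
#'   `diagnostics` (data.frame `folder`, `error`).
#' @export
discover_dashboards <- function(root) {
  if (!dir.exists(root)) stop("startup error: unreadable root ", root)
  subs <- list.dirs(root, recursive = FALSE)
  instances <- list()
  diags <- list()
  for (d in subs) {
    nm <- basename(d)
    res <- tryCatch(read_dashboard_config(d), error = function(e) e)
    if (inherits(res, "error")) {
      diags[[length(diags) + 1]] <- c(nm, conditionMessage(res))
    } else {
      instances[[nm]] <- res
    }
  }
  diagnostics <- if (length(diags) == 0) {
    data.frame(folder = character(), error = character(),
               stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, diags)
    data.frame(folder = m[, 1], error = m[, 2], stringsAsFactors = FALSE)
  }
  list(instances = instances, diagnostics = diagnostics)
}

#' Refresh a dashboard instance if its data changed
#'
#' Compares the content hash of the data files with the instance's
#' `data_version`. Unchanged content is a no-op (the same instance is
#' returned, so payloads remain byte-identical). Changed content triggers a
#' full atomic re-pipeline; if the new data fail validation, the previous
#' materialized state is retained and the failure is surfaced in the
#' instance status.
#'
#' @param instance a [materialize_dashboard()] result.
#' @return a `dashboard_instance` (new, previous, or previous + error note).
#' @export
refresh_dashboard <- function(instance) {
  stopifnot(inherits(instance, "dashboard_instance"))
  dv <- .data_version(instance$config)
  if (identical(dv, instance$data_version)) return(instance)
  new_inst <- tryCatch(materialize_dashboard(instance$config),
                       error = function(e) e)
  if (inherits(new_inst, "error")) {
    instance$status <- list(ok = FALSE,
                            last_error = conditionMessage(new_inst))
    return(instance)
  }
  new_inst
}

#' Serve a dashboard page as a JSON-ready payload
#'
#' Delegates to the payload builders; invalid parameters (unknown page,
#' non-displayable cell, unknown chart or indicator) yield a structured
#' error payload with a 4xx-style status instead of an R error. Identical
#' instance state and parameters always produce identical payloads.
#'
#' @param instance a materialized `dashboard_instance`.
#' @param page `"overview"`, `"analysis"`, or `"status"`.
#' @param params named list: for overview, optional `indicator` and `cell`
#'   (c(q, r)); for analysis, `cell` (required) plus optional `charts`,
#'   `normalization`, `indicator_filter`.
#' @return payload envelope list, or `list(error = TRUE, status, message)`.
#' @export
serve_page <- function(instance, page, params = list()) {
  stopifnot(inherits(instance, "dashboard_instance"))
  err <- function(status, message) list(error = TRUE, status = status,
                                        message = message)
  if (!page %in% c("overview", "analysis", "status")) {
    return(err(404L, paste0("unknown page '", page, "'")))
  }
  if (page == "status") {
    return(list(
      page = "status", title = instance$config$title,
      data_version = instance$data_version,
      last_refresh = instance$last_refresh,
      n_participants = instance$aggregates$n_participants,
      displayable_cells = nrow(instance$display$cells),
      suppression = instance$display$suppression,
      ok = instance$status$ok,
      last_error = instance$status$last_error
    ))
  }
  tryCatch({
    if (page == "overview") {
      indicator <- params$indicator
      if (is.null(indicator)) indicator <- "hiv_prevalence"
      build_overview_payload(
        instance$display, instance$global_values, instance$config$spec,
        active_indicator = indicator,
        selected_cell = params$cell,
        classification = instance$config$classification,
        data_version = instance$data_version,
        generated_at = instance$last_refresh
      )
    } else {
      if (is.null(params$cell)) stop("selection error: analysis needs a cell")
      charts <- params$charts
      if (is.null(charts)) charts <- instance$config$chart_menu
      normalization <- params$normalization
      if (is.null(normalization)) normalization <- "total_population"
      build_analysis_payload(
        instance$display, instance$aggregates, instance$bundle,
        cell = params$cell, spec = instance$config$spec,
        chart_menu = charts, normalization = normalization,
        indicator_filter = params$indicator_filter,
        data_version = instance$data_version,
        generated_at = instance$last_refresh
      )
    }
  }, error = function(e) err(400L, conditionMessage(e)))
}

#' Materialize a dashboard and dump its payloads to files
#'
#' The file-based equivalent of serving: writes `overview.json`, one
#' `analysis_<q>_<r>.json` per displayable cell (capped), and
#' `status.json` under `<folder>/build/`.
#'
#' @param folder dashboard folder.
#' @param max_cells cap on the number of per-cell analysis payload files.
#' @return the build directory, invisibly.
#' @export
build_dashboard <- function(folder, max_cells = 25) {
  config <- read_dashboard_config(folder)
  inst <- materialize_dashboard(config)
  out <- file.path(folder, "build")
  dir.create(out, showWarnings = FALSE)
  writeLines(payload_json(serve_page(inst, "overview")),
             file.path(out, "overview.json"))
  cells <- inst$display$cells
  n_dump <- min(nrow(cells), max_cells)
  ord <- order(-cells$participant_count)[seq_len(n_dump)]
  for (i in ord) {
    pl <- serve_page(inst, "analysis",
                     list(cell = c(cells$q[i], cells$r[i])))
    writeLines(payload_json(pl),
               file.path(out, sprintf("analysis_%d_%d.json",
                                      cells$q[i], cells$r[i])))
  }
  writeLines(payload_json(serve_page(inst, "status")),
             file.path(out, "status.json"))
  invisible(out)
}
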