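# Standard dataset formats: participant CSV + region GeoJSON, with strict
# validation at load time. The participant record is the atomic unit of the
# framework and is never exposed downstream below hex-cell granularity.

#' Canonical participant columns
#'
#' Column names of the participants file, in canonical order. Booleans are
#' encoded 0/1; `sex` is `female`/`male`; the three demographic fields are
#' free categorical labels (missing values become `"unknown"`).
#'
#' @export
participant_columns <- c(
  "participant_id", "lon", "lat",
  "hiv_positive", "knows_status", "on_art", "virally_suppressed",
  "sex", "age_years", "education", "relationship_status", "employment"
)

.bool_cols <- c("hiv_positive", "knows_status", "on_art", "virally_suppressed")
.cat_cols <- c("education", "relationship_status", "employment")

#' Load participant records from a delimited file
#'
#' Reads a comma-separated UTF-8 file with a header row, applies an optional
#' column mapping, validates each row, and returns accepted records together
#' with a row-level rejection report. The treatment cascade must nest
#' (suppressed implies on ART implies diagnosed implies HIV-positive); rows
#' violating the nesting are rejected, not coerced, because surveillance
#' integrity matters more than permissiveness. Input rows are always
#' conserved: accepted + rejected equals rows read.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (see [participant_columns]) to the names used in the file.
#' @return a list of class `participant_load` with elements `records` (a
#'   data.frame of validated records in canonical column order) and
#'   `rejected` (a data.frame with columns `row`, `participant_id`,
#'   `reason`; zero rows when everything validated).
#' @export
load_participants <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("participants file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("NA", ""))
  mapping <- stats::setNames(participant_columns, participant_columns)
  if (!is.null(schema)) mapping[names(schema)] <- schema
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[, unname(mapping), drop = FALSE]
  names(raw) <- participant_columns

  n <- nrow(raw)
  reason <- character(n)  # "" = accepted

  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad_coord <- is.na(lon) | is.na(lat)
  reason[bad_coord & reason == ""] <- "non-numeric coordinate"

  flags <- lapply(raw[.bool_cols], .parse_bool)
  bad_flag <- Reduce(`|`, lapply(flags, is.na))
  reason[bad_flag & reason == ""] <- "invalid cascade flag"

  ok_flags <- !bad_flag
  nest_bad <- rep(FALSE, n)
  nest_bad[ok_flags] <-
    (flags$knows_status[ok_flags] & !flags$hiv_positive[ok_flags]) |
    (flags$on_art[ok_flags] & !flags$knows_status[ok_flags]) |
    (flags$virally_suppressed[ok_flags] & !flags$on_art[ok_flags])
  reason[nest_bad & reason == ""] <- "cascade nesting"

  age <- suppressWarnings(as.numeric(raw$age_years))
  bad_age <- is.na(age) | age < 0 | age != floor(age)
  reason[bad_age & reason == ""] <- "invalid age"

  sex <- tolower(trimws(raw$sex))
  bad_sex <- !(sex %in% c("female", "male"))
  reason[bad_sex & reason == ""] <- "invalid sex"

  bad_id <- is.na(raw$participant_id) | trimws(raw$participant_id) == ""
  reason[bad_id & reason == ""] <- "missing participant id"

  keep <- reason == ""
  records <- data.frame(
    participant_id = raw$participant_id[keep],
    lon = lon[keep],
    lat = lat[keep],
    hiv_positive = flags$hiv_positive[keep],
    knows_status = flags$knows_status[keep],
    on_art = flags$on_art[keep],
    virally_suppressed = flags$virally_suppressed[keep],
    sex = sex[keep],
    age_years = as.integer(age[keep]),
    stringsAsFactors = FALSE
  )
  for (col in .cat_cols) {
    v <- trimws(raw[[col]])[keep]
    v[is.na(v) | v == ""] <- "unknown"
    records[[col]] <- v
  }
  rejected <- data.frame(
    row = which(!keep),
    participant_id = raw$participant_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  structure(list(records = records, rejected = rejected),
            class = "participant_load")
}

.parse_bool <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t")] <- TRUE
  out[x %in% c("0", "false", "f")] <- FALSE
  out
}

#' Write participant records to the canonical CSV format
#'
#' Booleans are written 0/1 and coordinates with 17 significant digits so
#' that a write/load round trip reproduces field values exactly.
#'
#' @param records data.frame of participant records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  out <- records[, participant_columns, drop = FALSE]
  for (col in .bool_cols) out[[col]] <- as.integer(out[[col]])
  out$lon <- sprintf("%.17g", out$lon)
  out$lat <- sprintf("%.17g", out$lat)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a study region
#'
#' @param boundary two-column matrix of lon/lat vertices of a simple polygon
#'   (closed or open ring).
#' @param layers optional named list of infrastructure layers; each layer is
#'   a list with elements `type` (`"point"` or `"line"`) and `coords`
#'   (two-column lon/lat matrix).
#' @return object of class `study_region` with elements `boundary` (open
#'   ring), `layers`, and `center` (lon/lat used as the planar projection
#'   center).
#' @export
study_region <- function(boundary, layers = list()) {
  boundary <- as.matrix(boundary)
  if (all(boundary[1, ] == boundary[nrow(boundary), ])) {
    boundary <- boundary[-nrow(boundary), , drop = FALSE]
  }
  if (nrow(boundary) < 3) stop("geometry error: boundary needs >= 3 vertices")
  if (!polygon_is_simple(boundary)) {
    stop("geometry error: boundary polygon is self-intersecting")
  }
  if (abs(polygon_area(boundary)) <= 0) {
    stop("geometry error: boundary polygon has zero area")
  }
  center <- c(mean(range(boundary[, 1])), mean(range(boundary[, 2])))
  structure(list(boundary = boundary, layers = layers, center = center),
            class = "study_region")
}

#' Load a study region from GeoJSON
#'
#' Expects a FeatureCollection with exactly one polygon feature carrying
#' property `role = "boundary"` (a bare single polygon feature is also
#' accepted). Features with `role = "layer"` and a `name` property are
#' attached as named infrastructure layers (points or lines, e.g. clinics
#' and roads).
#'
#' @param path path to a GeoJSON file.
#' @return a [study_region()].
#' @export
load_region <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("format error: not a GeoJSON Feature or FeatureCollection")
  boundary <- NULL
  layers <- list()
  for (f in feats) {
    geom <- f$geometry
    role <- f$properties$role
    if (identical(geom$type, "Polygon") &&
        (is.null(role) || identical(role, "boundary"))) {
      if (!is.null(boundary)) stop("format error: multiple boundary polygons")
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p) {
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))
      }))
      boundary <- ring
    } else if (identical(role, "layer")) {
      nm <- f$properties$name
      if (is.null(nm)) stop("format error: layer feature without a name")
      coords <- if (identical(geom$type, "Point")) {
        matrix(as.numeric(unlist(geom$coordinates)), ncol = 2)
      } else {
        do.call(rbind, lapply(geom$coordinates, function(p) {
          c(as.numeric(p[[1]]), as.numeric(p[[2]]))
        }))
      }
      type <- if (identical(geom$type, "LineString")) "line" else "point"
      if (is.null(layers[[nm]])) {
        layers[[nm]] <- list(type = type, coords = coords)
      } else {
        layers[[nm]]$coords <- rbind(layers[[nm]]$coords, coords)
      }
    }
  }
  if (is.null(boundary)) stop("format error: no boundary polygon feature")
  study_region(boundary, layers)
}

#' Write a study region to GeoJSON
#'
#' @param region a [study_region()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region <- function(region, path) {
  ring <- rbind(region$boundary, region$boundary[1, ])
  coord_list <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
  feats <- list(list(
    type = "Feature",
    properties = list(role = "boundary"),
    geometry = list(type = "Polygon", coordinates = list(coord_list))
  ))
  for (nm in names(region$layers)) {
    lyr <- region$layers[[nm]]
    if (identical(lyr$type, "line")) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(role = "layer", name = nm),
        geometry = list(
          type = "LineString",
          coordinates = lapply(seq_len(nrow(lyr$coords)),
                               function(i) as.numeric(lyr$coords[i, ]))
        )
      )
    } else {
      for (i in seq_len(nrow(lyr$coords))) {
        feats[[length(feats) + 1]] <- list(
          type = "Feature",
          properties = list(role = "layer", name = nm),
          geometry = list(type = "Point",
                          coordinates = as.numeric(lyr$coords[i, ]))
        )
      }
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  # 17 significant digits so a write/load round trip is vertex-identical
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Assemble a dataset bundle
#'
#' @param participants data.frame of validated participant records.
#' @param region a [study_region()].
#' @param as_of date of last refresh (defaults to today).
#' @return object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(participants, region, as_of = Sys.Date()) {
  stopifnot(inherits(region, "study_region"))
  structure(list(participants = participants, region = region,
                 as_of = as.Date(as_of)),
            class = "dataset_bundle")
}

#' Validate a dataset bundle
#'
#' Reports every invariant breach: duplicate participant ids, participants
#' located outside the region boundary, and cascade-nesting violations
#' (the latter cannot arise from [load_participants()] but are re-checked
#' so that programmatically built bundles get the same guarantees).
#'
#' @param bundle a [dataset_bundle()].
#' @return data.frame with columns `type`, `participant_id`, `detail`;
#'   zero rows if and only if the bundle is clean.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  p <- bundle$participants
  issues <- list()
  dup <- p$participant_id[duplicated(p$participant_id)]
  for (id in unique(dup)) {
    issues[[length(issues) + 1]] <- c("duplicate id", id, "participant_id not unique")
  }
  if (nrow(p) > 0) {
    # containment is tested in the region's planar projection — the same
    # geometry every other operation uses — not in raw degrees
    ctr <- bundle$region$center
    bnd <- project_planar(bundle$region$boundary, ctr)
    inside <- points_in_polygon(bnd, project_planar(cbind(p$lon, p$lat), ctr))
    for (i in which(!inside)) {
      issues[[length(issues) + 1]] <-
        c("out of region", p$participant_id[i],
          sprintf("point (%.6f, %.6f) outside boundary", p$lon[i], p$lat[i]))
    }
    bad_nest <- (p$knows_status & !p$hiv_positive) |
      (p$on_art & !p$knows_status) |
      (p$virally_suppressed & !p$on_art)
    for (i in which(bad_nest)) {
      issues[[length(issues) + 1]] <-
        c("cascade nesting", p$participant_id[i], "cascade flags do not nest")
    }
  }
  if (length(issues) == 0) {
    return(data.frame(type = character(), participant_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, issues)
  data.frame(type = m[, 1], participant_id = m[, 2], detail = m[, 3],
             stringsAsFactors = FALSE)
}

#' Write a bundle's files to a directory
#'
#' Emits `participants.csv` and `region.geojson` in the framework's standard
#' formats; loading them back reproduces the bundle.
#'
#' @param bundle a [dataset_bundle()].
#' @param directory output directory (created if absent).
#' @return named character vector of the two paths written, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(directory, "participants.csv")
  rp <- file.path(directory, "region.geojson")
  write_participants(bundle$participants, pp)
  write_region(bundle$region, rp)
  invisible(c(participants = pp, region = rp))
}

#' Load a bundle from a directory
#'
#' Counterpart of [write_bundle()].
#'
#' @param directory directory holding `participants.csv` and
#'   `region.geojson`.
#' @param as_of refresh date recorded on the bundle.
#' @return a [dataset_bundle()].
#' @export
load_bundle <- function(directory, as_of = Sys.Date()) {
  loaded <- load_participants(file.path(directory, "participants.csv"))
  if (nrow(loaded$rejected) > 0) {
    stop("bundle load rejected ", nrow(loaded$rejected), " row(s); first reason: ",
         loaded$rejected$reason[1])
  }
  region <- load_region(file.path(directory, "region.geojson"))
  dataset_bundle(loaded$records, region, as_of)
}
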