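#' The seven-code fishing ethogram
#'
#' Closed vocabulary of behaviours coded from camera footage of wolves at
#' fishing water sources: locomotion on the bank or in the water, the
#' three possible outcomes of a fishing attempt (successful, failed,
#' outcome not visible), and post-capture handling (carrying or caching a
#' fish). `"successful_fishing_attempt"` also covers records coded
#' "complete fishing attempt".
#'
#' @return character vector of the seven codes.
#' @export
ethogram_codes <- function() {
  c("on_creek_bank", "wading",
    "successful_fishing_attempt", "failed_fishing_attempt",
    "unknown_fishing_attempt", "carrying_fish", "caching_fish")
}

#' Evidence-source vocabulary
#' @return character vector of the recognised evidence sources.
#' @export
evidence_sources <- function() {
  c("cluster", "remote_camera", "camera_collar", "field_observation", "external")
}

# ---- trajectories -----------------------------------------------------------

#' Build a trajectory from planar fixes
#'
#' A trajectory is a tibble of time-ordered GPS fixes for one animal with
#' columns `animal_id`, `t` (POSIXct with time zone), `x`, `y` (metres on
#' a planar grid) and `interval_min` (the collar's programmed fix spacing
#' in minutes, e.g. 20 or 720).
#'
#' @param animal_id single label.
#' @param t POSIXct timestamps.
#' @param x,y planar coordinates in metres.
#' @param interval_min nominal fix interval in minutes.
#' @return a `fw_trajectory` tibble sorted by time.
#' @export
trajectory <- function(animal_id, t, x, y, interval_min) {
  assert_that(length(animal_id) == 1 || length(unique(animal_id)) == 1,
              "a trajectory holds a single animal_id")
  assert_that(inherits(t, "POSIXct"), "timestamps must be POSIXct")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "coordinates must be finite")
  assert_that(all(interval_min > 0), "nominal fix interval must be positive")
  tr <- tibble::tibble(animal_id = as.character(animal_id)[[1]],
                       t = t, x = as.numeric(x), y = as.numeric(y),
                       interval_min = as.numeric(interval_min))
  tr <- dplyr::arrange(tr, t)
  if (anyDuplicated(tr$t) > 0) {
    rlang::abort(sprintf("duplicate timestamps for animal '%s'", tr$animal_id[[1]]),
                 class = "fishwolf_schema_error")
  }
  class(tr) <- c("fw_trajectory", class(tr))
  tr
}

#' Read GPS fix tables into trajectories
#'
#' The fix table is delimited text with columns `animal_id`,
#' `timestamp` (ISO-8601), either `lon`/`lat` (geographic WGS84,
#' projected via `crs`) or `x`/`y` (already planar metres), and
#' `fix_interval_min`. One trajectory is returned per animal, time
#' sorted; duplicate (animal, timestamp) rows are an error rather than
#' silently deduplicated.
#'
#' @param path CSV file path.
#' @param crs projection spec (`"utm:15N"`, `"planar"`, or an `fw_crs`).
#'   Required (as a UTM spec) when the table carries lon/lat.
#' @param tz time zone for timestamps without an explicit offset
#'   (default `"America/Chicago"`).
#' @return named list of `fw_trajectory` tibbles keyed by animal id.
#' @export
read_fixes <- function(path, crs = "utm:15N", tz = "America/Chicago") {
  assert_that(file.exists(path), sprintf("fix table not found: %s", path),
              "fishwolf_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(timestamp = readr::col_character(),
                                                animal_id = readr::col_character()))
  if (nrow(df) == 0) {
    rlang::warn("fix table is empty; returning an empty collection")
    return(list())
  }
  need <- c("animal_id", "timestamp", "fix_interval_min")
  missing <- setdiff(need, names(df))
  has_ll <- all(c("lon", "lat") %in% names(df))
  has_xy <- all(c("x", "y") %in% names(df))
  if (!has_ll && !has_xy) missing <- c(missing, "lon/lat or x/y")
  assert_that(length(missing) == 0,
              sprintf("fix table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "fishwolf_schema_error")
  t <- parse_timestamps(df$timestamp, tz)
  if (has_ll) {
    crs <- as_fw_crs(crs)
    assert_that(crs$type == "utm",
                "lon/lat input needs a UTM projection spec (e.g. 'utm:15N')",
                "fishwolf_config_error")
    xy <- project_lonlat(df$lon, df$lat, crs)
  } else {
    xy <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  }
  df2 <- tibble::tibble(animal_id = as.character(df$animal_id), t = t,
                        x = xy[, 1], y = xy[, 2],
                        interval_min = as.numeric(df$fix_interval_min))
  out <- lapply(split(df2, df2$animal_id), function(d) {
    trajectory(d$animal_id[[1]], d$t, d$x, d$y, d$interval_min)
  })
  out[order(names(out))]
}

parse_timestamps <- function(ts, tz) {
  if (inherits(ts, "POSIXct")) return(lubridate::force_tz(ts, tz))
  t <- lubridate::parse_date_time(ts, orders = c("Ymd HMS", "Ymd HM", "Ymd"),
                                  tz = tz, quiet = TRUE)
  bad <- which(is.na(t) & !is.na(ts))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unparseable timestamp at row %d: '%s'",
                         bad[[1]], ts[[bad[[1]]]]),
                 class = "fishwolf_schema_error")
  }
  t
}

# ---- water features ---------------------------------------------------------

#' Construct a water feature
#'
#' A water feature is a river or creek centreline: an ordered polyline in
#' planar metres, optionally with point markers for beaver dams on or
#' near the line.
#'
#' @param feature_id identifier.
#' @param vertices two-column numeric matrix of polyline vertices (metres).
#' @param name display name (defaults to the id).
#' @param dam_points optional two-column matrix of dam marker points.
#' @return an object of class `water_feature`.
#' @export
water_feature <- function(feature_id, vertices, name = feature_id,
                          dam_points = NULL) {
  vertices <- as.matrix(vertices)
  assert_that(is.numeric(vertices) && ncol(vertices) == 2 && nrow(vertices) >= 2,
              "a water feature polyline needs >= 2 two-dimensional vertices",
              "fishwolf_geometry_error")
  seg <- diff(vertices)
  assert_that(all(rowSums(seg^2) > 0),
              sprintf("degenerate polyline in feature '%s': consecutive vertices coincide",
                      feature_id),
              "fishwolf_geometry_error")
  if (!is.null(dam_points)) {
    dam_points <- matrix(as.numeric(dam_points), ncol = 2)
  }
  structure(list(feature_id = as.character(feature_id), name = as.character(name),
                 vertices = unname(vertices), dam_points = dam_points),
            class = "water_feature")
}

#' Polyline length of a water feature
#' @param feature a `water_feature`.
#' @return length in metres.
#' @export
feature_length <- function(feature) {
  sum(sqrt(rowSums(diff(feature$vertices)^2)))
}

#' Read water features from GeoJSON or WKT
#'
#' Accepts a GeoJSON FeatureCollection whose features carry LineString or
#' MultiLineString geometries (creek/river centrelines) and optional
#' Point geometries interpreted as beaver-dam markers attached to the
#' nearest line; or a plain-text file of `LINESTRING (...)` WKT, one per
#' line. Coordinates are taken to be in the same planar metre grid as
#' the fixes unless `crs` is a UTM spec and coordinates look geographic.
#'
#' @param path file path (`.geojson`/`.json` or WKT text).
#' @param crs projection spec used to project lon/lat coordinates; pass
#'   `"planar"` (default) when the file is already in metres.
#' @return named list of `water_feature` objects.
#' @export
read_water_features <- function(path, crs = "planar") {
  assert_that(file.exists(path), sprintf("water feature file not found: %s", path),
              "fishwolf_io_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) {
    feats <- parse_geojson_features(txt)
  } else {
    feats <- parse_wkt_lines(txt)
  }
  crs <- as_fw_crs(crs)
  lines <- purrr::keep(feats, ~ .x$kind == "line")
  points <- purrr::keep(feats, ~ .x$kind == "point")
  assert_that(length(lines) > 0,
              "no line geometries found; water features must be LineStrings",
              "fishwolf_geometry_error")
  maybe_project <- function(m) {
    if (crs$type == "utm" && all(abs(m[, 1]) <= 360) && all(abs(m[, 2]) <= 90)) {
      project_lonlat(m[, 1], m[, 2], crs)
    } else m
  }
  out <- lapply(lines, function(f) {
    water_feature(f$id, maybe_project(f$coords), name = f$name %||% f$id)
  })
  names(out) <- vapply(out, function(f) f$feature_id, character(1))
  # attach each dam point to the nearest polyline
  for (p in points) {
    xy <- maybe_project(p$coords)
    d <- vapply(out, function(f) dist_point_polyline(xy[1, 1], xy[1, 2], f$vertices),
                numeric(1))
    k <- which.min(d)
    out[[k]]$dam_points <- rbind(out[[k]]$dam_points, xy)
  }
  out
}

parse_geojson_features <- function(txt) {
  gj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry %||% f
    id <- as.character(f$properties$feature_id %||% f$properties$id %||% f$id %||%
                         sprintf("feature_%d", i))
    nm <- f$properties$name
    coords_mat <- function(cc) {
      do.call(rbind, lapply(cc, function(v) c(v[[1]], v[[2]])))
    }
    if (identical(g$type, "LineString")) {
      out[[length(out) + 1]] <- list(kind = "line", id = id, name = nm,
                                     coords = coords_mat(g$coordinates))
    } else if (identical(g$type, "MultiLineString")) {
      for (j in seq_along(g$coordinates)) {
        out[[length(out) + 1]] <- list(kind = "line",
                                       id = if (length(g$coordinates) > 1)
                                         sprintf("%s_%d", id, j) else id,
                                       name = nm,
                                       coords = coords_mat(g$coordinates[[j]]))
      }
    } else if (identical(g$type, "Point")) {
      out[[length(out) + 1]] <- list(kind = "point", id = id, name = nm,
                                     coords = matrix(unlist(g$coordinates), ncol = 2))
    } else {
      rlang::abort(sprintf("unsupported geometry type '%s'; lines (and dam points) required",
                           g$type %||% "<none>"),
                   class = "fishwolf_geometry_error")
    }
  }
  out
}

parse_wkt_lines <- function(txt) {
  rows <- trimws(strsplit(txt, "\n", fixed = TRUE)[[1]])
  rows <- rows[nzchar(rows)]
  out <- list()
  for (i in seq_along(rows)) {
    m <- regmatches(rows[[i]], regexec("^LINESTRING\\s*\\((.*)\\)\\s*$", rows[[i]],
                                       ignore.case = TRUE))[[1]]
    assert_that(length(m) == 2,
                sprintf("cannot parse WKT line %d (only LINESTRING is supported)", i),
                "fishwolf_geometry_error")
    pts <- strsplit(m[[2]], ",")[[1]]
    coords <- do.call(rbind, lapply(pts, function(p) {
      as.numeric(strsplit(trimws(p), "\\s+")[[1]][1:2])
    }))
    out[[i]] <- list(kind = "line", id = sprintf("feature_%d", i), name = NULL,
                     coords = coords)
  }
  out
}

# ---- camera records ---------------------------------------------------------

#' Read camera-trap record tables
#'
#' CSV with columns `camera_id`, `timestamp`, `media` (photo|video),
#' `n_wolves` (>= 1), `collar_status` (collared|uncollared|unknown),
#' optional `wolf_id`, and `behaviour` drawn from the seven-code
#' ethogram. Records are returned sorted by (camera_id, timestamp).
#'
#' @param path CSV file path.
#' @param tz time zone for timestamps (default `"America/Chicago"`).
#' @return tibble of camera records.
#' @export
read_camera_records <- function(path, tz = "America/Chicago") {
  assert_that(file.exists(path), sprintf("camera record table not found: %s", path),
              "fishwolf_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(timestamp = readr::col_character(),
                                                camera_id = readr::col_character()))
  need <- c("camera_id", "timestamp", "media", "n_wolves", "collar_status", "behaviour")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0,
              sprintf("camera table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "fishwolf_schema_error")
  camera_records(
    camera_id = df$camera_id,
    t = parse_timestamps(df$timestamp, tz),
    media = df$media,
    n_wolves = df$n_wolves,
    collar_status = df$collar_status,
    wolf_id = if ("wolf_id" %in% names(df)) df$wolf_id else NA_character_,
    behaviour = df$behaviour
  )
}

#' Construct a camera-record tibble with schema validation
#'
#' @param camera_id,t,media,n_wolves,collar_status,wolf_id,behaviour
#'   record fields; see [read_camera_records()].
#' @return tibble sorted by (camera_id, t).
#' @export
camera_records <- function(camera_id, t, media = "video", n_wolves = 1L,
                           collar_status = "unknown", wolf_id = NA_character_,
                           behaviour) {
  bad <- setdiff(unique(behaviour), ethogram_codes())
  assert_that(length(bad) == 0,
              sprintf("unknown behaviour code(s): %s; allowed codes are: %s",
                      paste(bad, collapse = ", "),
                      paste(ethogram_codes(), collapse = ", ")),
              "fishwolf_vocabulary_error")
  assert_that(all(n_wolves >= 1), "n_wolves must be >= 1", "fishwolf_schema_error")
  assert_that(all(media %in% c("photo", "video")),
              "media must be 'photo' or 'video'", "fishwolf_schema_error")
  assert_that(all(collar_status %in% c("collared", "uncollared", "unknown")),
              "collar_status must be collared|uncollared|unknown",
              "fishwolf_schema_error")
  out <- tibble::tibble(camera_id = as.character(camera_id), t = t,
                        media = as.character(media),
                        n_wolves = as.integer(n_wolves),
                        collar_status = as.character(collar_status),
                        wolf_id = as.character(wolf_id),
                        behaviour = as.character(behaviour))
  dplyr::arrange(out, camera_id, t)
}

# ---- cluster annotations ----------------------------------------------------

#' Read cluster field-annotation tables
#'
#' CSV keyed by `cluster_id` with logical evidence flags from the ground
#' search of each GPS cluster: `fresh_fish_remains`, `wolf_sign_abundant`,
#' `other_predator_sign`, `remains_old`, and optional `fish_species`,
#' `water_depth_class` (`lt_1m`/`ge_1m`/`unknown`) and
#' `active_beaver_dam_nearby`.
#'
#' @param path CSV file path.
#' @return tibble of annotations.
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), sprintf("annotation table not found: %s", path),
              "fishwolf_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cluster_id", "fresh_fish_remains", "wolf_sign_abundant",
            "other_predator_sign", "remains_old")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0,
              sprintf("annotation table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "fishwolf_schema_error")
  for (col in setdiff(need, "cluster_id")) df[[col]] <- as.logical(df[[col]])
  bad <- df$fresh_fish_remains & df$remains_old
  assert_that(!any(bad, na.rm = TRUE),
              "remains cannot be both fresh and old for the same record",
              "fishwolf_schema_error")
  if (!"fish_species" %in% names(df)) df$fish_species <- NA_character_
  if (!"water_depth_class" %in% names(df)) df$water_depth_class <- "unknown"
  if (!"active_beaver_dam_nearby" %in% names(df)) df$active_beaver_dam_nearby <- NA
  tibble::as_tibble(df)
}
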