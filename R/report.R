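#' Run configuration
#'
#' The pipeline parameters with their standard defaults: 200 m cluster
#' radius with at least 2 fixes and a gap bound of 3 nominal intervals,
#' the 10-min camera event gap, 20 m and 500 m occupancy buffers, a
#' 20:00-06:00 night window, and the default behaviour precedence. The
#' config is echoed into every manifest for provenance.
#'
#' @param crs projection spec for fix input.
#' @param tz local time zone.
#' @param cluster_radius metres.
#' @param min_cluster_fixes minimum fixes per cluster.
#' @param max_gap_multiplier cluster gap bound in nominal intervals.
#' @param event_gap_min camera event gap (minutes).
#' @param buffer_radii occupancy radii (metres).
#' @param night_window local night hours `c(from, to)`.
#' @param precedence behaviour precedence list.
#' @param seed integer seed for any randomness.
#' @return a `run_config` list.
#' @export
run_config <- function(crs = "utm:15N", tz = "America/Chicago",
                       cluster_radius = 200, min_cluster_fixes = 2L,
                       max_gap_multiplier = 3, event_gap_min = 10,
                       buffer_radii = c(20, 500), night_window = c(20L, 6L),
                       precedence = default_precedence(), seed = 1L) {
  structure(list(crs = crs, tz = tz, cluster_radius = cluster_radius,
                 min_cluster_fixes = min_cluster_fixes,
                 max_gap_multiplier = max_gap_multiplier,
                 event_gap_min = event_gap_min, buffer_radii = buffer_radii,
                 night_window = night_window, precedence = precedence,
                 seed = as.integer(seed)),
            class = "run_config")
}

# ---- dataset round trip -----------------------------------------------------

#' Write water features as GeoJSON
#' @param features named list of `water_feature` objects.
#' @param path output path.
#' @export
write_water_features_geojson <- function(features, path) {
  feat_json <- list()
  for (f in features) {
    feat_json[[length(feat_json) + 1]] <- list(
      type = "Feature",
      properties = list(feature_id = f$feature_id, name = f$name),
      geometry = list(type = "LineString",
                      coordinates = unname(apply(f$vertices, 1, as.list, simplify = FALSE)))
    )
    if (!is.null(f$dam_points)) {
      for (i in seq_len(nrow(f$dam_points))) {
        feat_json[[length(feat_json) + 1]] <- list(
          type = "Feature",
          properties = list(feature_id = paste0(f$feature_id, "_dam"), kind = "dam"),
          geometry = list(type = "Point",
                          coordinates = as.list(f$dam_points[i, ]))
        )
      }
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feat_json),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

fmt_time <- function(t, tz) format(t, "%Y-%m-%d %H:%M:%S", tz = tz)

#' Simulate a dataset and write it to a directory
#'
#' Runs the generator end to end: trajectory, GPS clusters, ground-search
#' annotations, camera records; writes `fixes.csv`,
#' `water_features.geojson`, `camera_records.csv`,
#' `cluster_annotations.csv` and `ground_truth.json` (all the formats
#' the readers consume), creating the directory if needed.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return (invisibly) list of written paths plus the in-memory objects.
#' @export
run_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_trajectory(config)
  traj <- sim$trajectory
  clusters <- detect_clusters(traj)
  ann <- simulate_annotations(clusters, sim$truth, config)
  cam <- simulate_camera_records(config, sim$truth)
  rlang::inform(sprintf("simulated %d fixes, %d clusters, %d camera records",
                        nrow(traj), nrow(clusters), nrow(cam$records)))

  fixes_path <- file.path(dir, "fixes.csv")
  readr::write_csv(tibble::tibble(animal_id = traj$animal_id,
                                  timestamp = fmt_time(traj$t, config$tz),
                                  x = traj$x, y = traj$y,
                                  fix_interval_min = traj$interval_min),
                   fixes_path)
  water_path <- file.path(dir, "water_features.geojson")
  write_water_features_geojson(list(config$creek), water_path)
  cam_path <- file.path(dir, "camera_records.csv")
  readr::write_csv(dplyr::mutate(cam$records,
                                 timestamp = fmt_time(.data$t, config$tz),
                                 .keep = "unused"),
                   cam_path)
  ann_path <- file.path(dir, "cluster_annotations.csv")
  readr::write_csv(ann$annotations, ann_path)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    animal_id = config$animal_id,
    tz = config$tz,
    bouts = data.frame(date = as.character(sim$truth$bouts$date),
                       start = fmt_time(sim$truth$bouts$start, config$tz),
                       end = fmt_time(sim$truth$bouts$end, config$tz)),
    true_period = as.character(sim$truth$true_period),
    true_event_partition = cam$true_event_partition,
    true_fishing_cluster_ids = ann$true_ids,
    confounded_cluster_ids = ann$confounded_ids
  ), truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(paths = c(fixes = fixes_path, water = water_path,
                           camera = cam_path, annotations = ann_path,
                           truth = truth_path),
                 trajectory = traj, clusters = clusters,
                 annotations = ann, camera = cam, truth = sim$truth))
}

# ---- period table (cohort) --------------------------------------------------

#' Read a wolf fishing-period table
#'
#' Reads a cohort table with columns `year`, `wolf_id`, `pack`,
#' `social_status`, `sex`, `collar_fix_interval`, `waterway`,
#' `period_start`, `period_end`, `defined_by`. Rows without dates (e.g.
#' a failed collar) keep `NA` period fields — an absence, not a
#' zero-length period. Inclusive period lengths are computed for dated
#' rows.
#'
#' @param path CSV path; defaults to the bundled Greater Voyageurs
#'   cohort table.
#' @return tibble with `length_days` added.
#' @export
read_period_table <- function(path = system.file("extdata", "gve_fishing_periods.csv",
                                                 package = "fishwolf")) {
  assert_that(file.exists(path), sprintf("period table not found: %s", path),
              "fishwolf_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(period_start = readr::col_date(),
                                                period_end = readr::col_date(),
                                                .default = readr::col_character()))
  df$year <- as.integer(df$year)
  df$length_days <- ifelse(is.na(df$period_start) | is.na(df$period_end),
                           NA_integer_,
                           inclusive_days(df$period_start, df$period_end))
  tibble::as_tibble(df)
}

#' Cohort summary of a period table
#'
#' Counts distinct collared wolves (rows whose `wolf_id` is a real
#' collar id, not the pooled `uncollared`/`unknown` group) and distinct
#' waterways (compound entries such as `"Ash River & Black Duck"` split
#' on `&`), and, when the size of the full collared cohort is given, the
#' integer percentage that fished.
#'
#' @param tbl period table from [read_period_table()].
#' @param total_collared optional size of the studied collared cohort.
#' @return list with `n_collared_wolves`, `n_waterways`,
#'   `pct_of_collared` (`NA` without `total_collared`).
#' @export
cohort_summary <- function(tbl, total_collared = NULL) {
  ids <- setdiff(unique(tbl$wolf_id), c("uncollared", "unknown", NA))
  ww <- unlist(strsplit(unique(tbl$waterway), "\\s*&\\s*"))
  ww <- unique(trimws(ww[!is.na(ww) & nzchar(ww)]))
  list(n_collared_wolves = length(ids),
       n_waterways = length(ww),
       pct_of_collared = if (is.null(total_collared)) NA_integer_
                         else pct_int(length(ids), total_collared))
}

#' Fishing evidence records from dated camera events
#'
#' Each dated event yields one evidence record. Collared events with a
#' known wolf id are attributed to that wolf; other events are pooled
#' into an `uncollared_<year>` group, since individuals without collars
#' cannot be told apart on camera. Date-less events are skipped (they
#' contribute to behaviour tallies only).
#'
#' @param events event tibble from [segment_events()].
#' @param feature_id water feature the cameras sit on.
#' @param tz local time zone.
#' @return evidence tibble.
#' @export
camera_evidence_from_events <- function(events, feature_id, tz = "America/Chicago") {
  ev <- events[!is.na(events$start_t), ]
  if (nrow(ev) == 0) return(empty_evidence())
  wolf <- vapply(seq_len(nrow(ev)), function(i) {
    r <- ev$records[[i]]
    ids <- unique(r$wolf_id[r$collar_status == "collared" & !is.na(r$wolf_id)])
    if (ev$collar_class[[i]] == "collared" && length(ids) > 0) ids[[1]]
    else sprintf("uncollared_%d", lubridate::year(as.Date(ev$start_t[[i]], tz = tz)))
  }, character(1))
  tibble::tibble(animal_id = wolf,
                 date = as.Date(ev$start_t, tz = tz),
                 source = "remote_camera",
                 feature_id = feature_id,
                 distance_m = NA_real_,
                 cluster_id = NA_character_)
}

# ---- analyze ----------------------------------------------------------------

#' Analyse a dataset directory end to end
#'
#' Reads fixes, water features, camera records and cluster annotations
#' from `dir`; detects and classifies GPS clusters, segments camera
#' events and tallies the ethogram, pools evidence into fishing periods,
#' computes before/during/after buffer occupancy for 20-min collars, and
#' pools activity profiles. Writes `clusters.csv`, `events.csv`,
#' `evidence.csv`, `periods.csv`, `occupancy.csv`, `hour_histogram.csv`,
#' `date_histogram.csv`, `summary.json` and `manifest.json` under
#' `out_dir`.
#'
#' @param dir dataset directory (as written by [run_simulate()], or any
#'   directory with the same file layout).
#' @param config a [run_config()].
#' @param out_dir output directory (default `file.path(dir, "analysis")`).
#' @return (invisibly) list with all computed tables and summaries.
#' @export
run_analyze <- function(dir, config = run_config(), out_dir = file.path(dir, "analysis")) {
  paths <- c(fixes = file.path(dir, "fixes.csv"),
             water = file.path(dir, "water_features.geojson"),
             camera = file.path(dir, "camera_records.csv"),
             annotations = file.path(dir, "cluster_annotations.csv"))
  for (nm in names(paths)) {
    assert_that(file.exists(paths[[nm]]),
                sprintf("missing input file '%s' (%s)", nm, paths[[nm]]),
                "fishwolf_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  trajs <- read_fixes(paths[["fixes"]], crs = config$crs, tz = config$tz)
  features <- read_water_features(paths[["water"]])
  records <- read_camera_records(paths[["camera"]], tz = config$tz)
  annotations <- read_annotations(paths[["annotations"]])
  rlang::inform(sprintf("inputs: %d trajectories, %d features, %d camera records, %d annotations",
                        length(trajs), length(features), nrow(records),
                        nrow(annotations)))

  # clusters per 20-min trajectory (sub-daily collars only)
  clusters <- dplyr::bind_rows(lapply(trajs, function(tr) {
    if (tr$interval_min[[1]] > 60) return(empty_clusters())
    detect_clusters(tr, radius = config$cluster_radius,
                    min_fixes = config$min_cluster_fixes,
                    max_gap_min = config$max_gap_multiplier * tr$interval_min[[1]])
  }))
  cluster_evidence <- fishing_evidence_from_clusters(clusters, annotations,
                                                     features, tz = config$tz)
  rlang::inform(sprintf("clusters: %d detected, %d classified as fishing",
                        nrow(clusters), nrow(cluster_evidence)))

  events <- segment_events(records, gap_min = config$event_gap_min)
  if (nrow(events) > 0) events <- assign_primary_behaviour(events, config$precedence)
  event_summary <- summarize_events(events)
  camera_feature <- if (nrow(records) > 0 && length(features) > 0)
    names(features)[[1]] else NA_character_
  camera_evidence <- camera_evidence_from_events(events, camera_feature,
                                                 tz = config$tz)
  rlang::inform(sprintf("camera: %d records, %d events", nrow(records), nrow(events)))

  evidence <- dplyr::bind_rows(cluster_evidence, camera_evidence)
  periods <- infer_all_periods(evidence)
  period_summary <- summarize_periods(periods)

  # occupancy phases for collared animals with a period and a 20-min collar
  occupancy <- list(); during_profiles <- list()
  for (i in seq_len(nrow(periods))) {
    aid <- periods$animal_id[[i]]
    if (!aid %in% names(trajs)) next
    tr <- trajs[[aid]]
    if (tr$interval_min[[1]] != 20) next
    feat_id <- evidence$feature_id[evidence$animal_id == aid & !is.na(evidence$feature_id)]
    feat <- features[[if (length(feat_id) > 0) feat_id[[1]] else names(features)[[1]]]]
    pc <- phase_comparison(tr, feat, periods[i, ], radii = config$buffer_radii,
                           tz = config$tz)
    occupancy[[length(occupancy) + 1]] <- pc$summary
    nm <- sprintf("during_%g", min(config$buffer_radii))
    if (nm %in% names(pc$profiles)) {
      during_profiles[[length(during_profiles) + 1]] <- pc$profiles[[nm]]
    }
  }
  occupancy <- if (length(occupancy) > 0) dplyr::bind_rows(occupancy) else
    tibble::tibble(animal_id = character(0), phase = character(0),
                   radius = numeric(0), window_start = as.Date(character(0)),
                   window_end = as.Date(character(0)), covered = logical(0),
                   hours_per_day = numeric(0))
  profiles <- if (length(during_profiles) > 0)
    activity_profiles(during_profiles, config$night_window) else NULL

  # ---- write outputs
  cl_out <- clusters
  if (nrow(cl_out) > 0) {
    ann <- annotations[match(cl_out$cluster_id, annotations$cluster_id), ]
    cl_out$is_fishing <- !is.na(ann$cluster_id) & is_fishing_cluster(ann)
    nearest <- cluster_evidence[match(cl_out$cluster_id, cluster_evidence$cluster_id), ]
    cl_out$nearest_feature <- nearest$feature_id
    cl_out$distance_m <- nearest$distance_m
  }
  readr::write_csv(dplyr::select(cl_out, -dplyr::any_of(c("first_idx", "last_idx"))),
                   file.path(out_dir, "clusters.csv"))
  readr::write_csv(dplyr::select(events, -dplyr::any_of("records")),
                   file.path(out_dir, "events.csv"))
  readr::write_csv(evidence, file.path(out_dir, "evidence.csv"))
  readr::write_csv(periods, file.path(out_dir, "periods.csv"))
  readr::write_csv(occupancy, file.path(out_dir, "occupancy.csv"))
  if (!is.null(profiles)) {
    readr::write_csv(tibble::tibble(hour = 0:23, n = as.integer(profiles$by_hour)),
                     file.path(out_dir, "hour_histogram.csv"))
    readr::write_csv(profiles$by_date, file.path(out_dir, "date_histogram.csv"))
  }
  summary <- list(
    n_clusters = nrow(clusters),
    n_fishing_clusters = nrow(cluster_evidence),
    n_events = event_summary$n_events,
    event_summary = list(
      by_category = event_summary$by_category,
      collared = event_summary$collared,
      uncollared_or_unknown = event_summary$uncollared_or_unknown),
    periods = periods,
    period_summary = period_summary,
    occupancy = occupancy,
    night_share = if (!is.null(profiles)) profiles$night_share else NA_real_
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  manifest <- list(config = unclass(config),
                   inputs = as.list(tools::md5sum(unname(paths))),
                   package_version = as.character(utils::packageVersion("fishwolf")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(trajectories = trajs, features = features, clusters = cl_out,
                 events = events, event_summary = event_summary,
                 evidence = evidence, periods = periods,
                 period_summary = period_summary, occupancy = occupancy,
                 profiles = profiles, out_dir = out_dir))
}

# ---- validate ---------------------------------------------------------------

#' Validate pipeline recovery against simulated ground truth
#'
#' Re-runs the analysis over a simulated dataset directory and compares
#' it with the stored ground truth: fishing-period endpoint errors in
#' days, precision/recall of fishing-cluster classification against the
#' expected positives (true bout clusters minus deliberately confounded
#' ones), and agreement of the camera event partition with the true
#' partition (fraction of adjacent record pairs on which the
#' same-event/different-event decision matches).
#'
#' @param dir dataset directory containing `ground_truth.json`.
#' @param config a [run_config()].
#' @return list of recovery metrics (also written to
#'   `validation.json` in the analysis directory).
#' @export
run_validate <- function(dir, config = run_config()) {
  truth_path <- file.path(dir, "ground_truth.json")
  assert_that(file.exists(truth_path), "ground_truth.json not found in dataset dir",
              "fishwolf_io_error")
  truth <- jsonlite::fromJSON(truth_path)
  res <- run_analyze(dir, config)

  expected_ids <- setdiff(truth$true_fishing_cluster_ids %||% character(0),
                          truth$confounded_cluster_ids %||% character(0))
  pred_ids <- res$clusters$cluster_id[isTRUE_vec(res$clusters$is_fishing)]
  tp <- length(intersect(pred_ids, expected_ids))
  precision <- if (length(pred_ids) > 0) tp / length(pred_ids) else NA_real_
  recall <- if (length(expected_ids) > 0) tp / length(expected_ids) else NA_real_

  period_err <- c(start = NA_real_, end = NA_real_)
  has_truth_period <- length(truth$true_period) == 2
  p <- res$periods[res$periods$animal_id == truth$animal_id, ]
  if (has_truth_period && nrow(p) == 1) {
    period_err <- c(
      start = as.numeric(p$start_date[[1]] - as.Date(truth$true_period[[1]])),
      end = as.numeric(p$end_date[[1]] - as.Date(truth$true_period[[2]])))
  } else if (!has_truth_period && nrow(p) == 0) {
    rlang::inform("no true bouts and no inferred period: recovery metrics are vacuous")
  } else if (has_truth_period && nrow(p) == 0) {
    rlang::warn("ground truth has a period but none was inferred")
  }

  truth_part <- as.integer(truth$true_event_partition %||% integer(0))
  records <- read_camera_records(file.path(dir, "camera_records.csv"), tz = config$tz)
  records <- dplyr::arrange(records, .data$camera_id, .data$t)
  agree <- NA_real_
  if (nrow(records) == length(truth_part) && length(truth_part) > 1) {
    ev <- segment_events(records, gap_min = config$event_gap_min)
    pred_part <- rep(seq_len(nrow(ev)), times = ev$n_records)
    same_pred <- diff(pred_part) == 0
    same_true <- diff(truth_part) == 0
    agree <- mean(same_pred == same_true)
  } else if (nrow(records) != length(truth_part)) {
    rlang::abort("ground truth partition does not match the camera records",
                 class = "fishwolf_validation_error")
  }

  metrics <- list(period_start_error_days = unname(period_err[["start"]]),
                  period_end_error_days = unname(period_err[["end"]]),
                  cluster_precision = precision, cluster_recall = recall,
                  n_expected_fishing_clusters = length(expected_ids),
                  n_predicted_fishing_clusters = length(pred_ids),
                  event_partition_agreement = agree)
  jsonlite::write_json(metrics, file.path(res$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  metrics
}

isTRUE_vec <- function(v) !is.na(v) & v
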