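#' Detect GPS clusters by the anchor rule
#'
#' A cluster is two or more consecutive fixes within `radius` metres of
#' the first fix (the anchor) of the cluster. The scan is greedy and
#' left-to-right: anchor at the current fix, extend while the next
#' consecutive fix lies within `radius` of the anchor and the time gap to
#' the previous member does not exceed `max_gap_min`; emit when at least
#' `min_fixes` members accumulated, then resume at the first fix outside
#' the cluster. Membership is always tested against the anchor, never a
#' running centroid, so clusters are disjoint, ordered, and made of
#' consecutive trajectory records.
#'
#' The gap bound exists because "consecutive" is ill-defined under missed
#' fixes: without it, a wolf that leaves and returns half a day later
#' could be glued into one day-spanning cluster. The default is three
#' nominal fix intervals.
#'
#' @param traj an `fw_trajectory` (time-sorted; enforced).
#' @param radius cluster radius in metres (default 200).
#' @param min_fixes minimum members per cluster (default 2).
#' @param max_gap_min maximum minutes between consecutive members;
#'   default `3 * interval_min` of the trajectory.
#' @return tibble with one row per cluster: `cluster_id`, `animal_id`,
#'   `start_t`, `end_t`, `n_fixes`, `anchor_x`, `anchor_y`, `centroid_x`,
#'   `centroid_y`, and member row indices `first_idx`, `last_idx` into
#'   the trajectory.
#' @export
detect_clusters <- function(traj, radius = 200, min_fixes = 2L,
                            max_gap_min = NULL) {
  assert_that(radius > 0, "cluster radius must be positive",
              "fishwolf_parameter_error")
  assert_that(min_fixes >= 2, "min_fixes must be at least 2",
              "fishwolf_parameter_error")
  assert_that(!is.unsorted(traj$t, strictly = TRUE),
              "trajectory must be strictly time-sorted",
              "fishwolf_precondition_error")
  max_gap_min <- max_gap_min %||% (3 * traj$interval_min[[1]])
  n <- nrow(traj)
  x <- traj$x; y <- traj$y
  gap_ok <- c(TRUE, diff(as.numeric(traj$t)) / 60 <= max_gap_min)
  first_idx <- integer(0); last_idx <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j + 1L <= n && gap_ok[[j + 1L]] &&
           (x[[j + 1L]] - x[[i]])^2 + (y[[j + 1L]] - y[[i]])^2 <= radius^2) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_fixes) {
      first_idx <- c(first_idx, i)
      last_idx <- c(last_idx, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(first_idx) == 0) return(empty_clusters())
  tibble::tibble(
    cluster_id = sprintf("%s_c%03d", traj$animal_id[[1]], seq_along(first_idx)),
    animal_id = traj$animal_id[[1]],
    start_t = traj$t[first_idx],
    end_t = traj$t[last_idx],
    n_fixes = last_idx - first_idx + 1L,
    anchor_x = x[first_idx],
    anchor_y = y[first_idx],
    centroid_x = vapply(seq_along(first_idx),
                        function(k) mean(x[first_idx[[k]]:last_idx[[k]]]), numeric(1)),
    centroid_y = vapply(seq_along(first_idx),
                        function(k) mean(y[first_idx[[k]]:last_idx[[k]]]), numeric(1)),
    first_idx = first_idx,
    last_idx = last_idx
  )
}

empty_clusters <- function() {
  tibble::tibble(cluster_id = character(0), animal_id = character(0),
                 start_t = as.POSIXct(character(0)), end_t = as.POSIXct(character(0)),
                 n_fixes = integer(0), anchor_x = numeric(0), anchor_y = numeric(0),
                 centroid_x = numeric(0), centroid_y = numeric(0),
                 first_idx = integer(0), last_idx = integer(0))
}

#' Classify annotated clusters as fishing sites
#'
#' A cluster is a fishing site when the ground search found fresh fish
#' remains (scales, gill plates, blood, fins, bones) with abundant wolf
#' sign, no sign of other predators (bear, raccoon, otter), and the
#' remains were not old — old remains may mean scavenging rather than
#' active fishing. Missing flags count as absent evidence (FALSE) and are
#' reported via a message.
#'
#' @param annotation annotation tibble (see [read_annotations()]); may be
#'   one or many rows.
#' @return logical vector, one element per annotation row.
#' @export
is_fishing_cluster <- function(annotation) {
  flags <- c("fresh_fish_remains", "wolf_sign_abundant",
             "other_predator_sign", "remains_old")
  n_missing <- sum(vapply(flags, function(f) sum(is.na(annotation[[f]])), numeric(1)))
  if (n_missing > 0) {
    rlang::inform(sprintf("%d missing evidence flag(s) treated as FALSE", n_missing))
  }
  na_false <- function(v) !is.na(v) & v
  na_false(annotation$fresh_fish_remains) &
    na_false(annotation$wolf_sign_abundant) &
    !na_false(annotation$other_predator_sign) &
    !na_false(annotation$remains_old)
}

#' Build fishing-evidence records from classified clusters
#'
#' Each fishing cluster yields one evidence record carrying the animal,
#' the local calendar date of the cluster start, the nearest water
#' feature and the centroid's distance to it.
#'
#' @param clusters cluster tibble from [detect_clusters()].
#' @param annotations annotation tibble keyed by `cluster_id`.
#' @param features named list of `water_feature` objects.
#' @param tz local time zone used to date evidence.
#' @return tibble of evidence records (`animal_id`, `date`, `source`,
#'   `feature_id`, `distance_m`, `cluster_id`).
#' @export
fishing_evidence_from_clusters <- function(clusters, annotations, features,
                                           tz = "America/Chicago") {
  assert_that(length(features) > 0, "no water features loaded",
              "fishwolf_config_error")
  if (nrow(clusters) == 0) return(empty_evidence())
  ann <- annotations[match(clusters$cluster_id, annotations$cluster_id), ]
  keep <- !is.na(ann$cluster_id) & is_fishing_cluster(ann)
  cl <- clusters[keep, ]
  if (nrow(cl) == 0) return(empty_evidence())
  dists <- vapply(seq_len(nrow(cl)), function(i) {
    vapply(features, function(f)
      dist_point_polyline(cl$centroid_x[[i]], cl$centroid_y[[i]], f$vertices),
      numeric(1))
  }, numeric(length(features)))
  dists <- matrix(dists, nrow = length(features))
  nearest <- apply(dists, 2, which.min)
  tibble::tibble(
    animal_id = cl$animal_id,
    date = as.Date(cl$start_t, tz = tz),
    source = "cluster",
    feature_id = names(features)[nearest],
    distance_m = dists[cbind(nearest, seq_len(nrow(cl)))],
    cluster_id = cl$cluster_id
  )
}

empty_evidence <- function() {
  tibble::tibble(animal_id = character(0), date = as.Date(character(0)),
                 source = character(0), feature_id = character(0),
                 distance_m = numeric(0), cluster_id = character(0))
}
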