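#' Segment camera records into events by the gap rule
#'
#' An event is a maximal series of photos/videos at one camera where the
#' time elapsed between sequential records is `gap_min` minutes or less
#' (a gap of exactly `gap_min` stays within the event; a longer gap
#' starts a new one). Records from different cameras never merge. The
#' events partition the records.
#'
#' @param records camera-record tibble (see [camera_records()]).
#' @param gap_min inter-record gap threshold in minutes (default 10).
#' @return tibble with one row per event: `event_id`, `camera_id`,
#'   `start_t`, `end_t`, `duration_s`, `n_records`, `n_wolves_max`,
#'   `collar_class` (`collared` if any record in the event shows a
#'   collar, else `uncollared_or_unknown`), and a nested `records`
#'   list-column holding each event's records.
#' @export
segment_events <- function(records, gap_min = 10) {
  records <- dplyr::arrange(records, camera_id, t)
  if (nrow(records) == 0) {
    return(tibble::tibble(event_id = character(0), camera_id = character(0),
                          start_t = as.POSIXct(character(0)),
                          end_t = as.POSIXct(character(0)),
                          duration_s = numeric(0), n_records = integer(0),
                          n_wolves_max = integer(0), collar_class = character(0),
                          records = list()))
  }
  new_cam <- c(TRUE, records$camera_id[-1] != records$camera_id[-nrow(records)])
  gap <- c(Inf, diff(as.numeric(records$t)) / 60)
  new_event <- new_cam | gap > gap_min
  eid <- cumsum(new_event)
  records$..event <- eid
  ev <- dplyr::group_by(records, .data$..event)
  out <- dplyr::summarise(
    ev,
    camera_id = .data$camera_id[[1]],
    start_t = min(.data$t),
    end_t = max(.data$t),
    duration_s = as.numeric(difftime(max(.data$t), min(.data$t), units = "secs")),
    n_records = dplyr::n(),
    n_wolves_max = max(.data$n_wolves),
    collar_class = if (any(.data$collar_status == "collared"))
      "collared" else "uncollared_or_unknown",
    .groups = "drop"
  )
  out$records <- unname(lapply(split(dplyr::select(records, -"..event"), eid),
                               tibble::as_tibble))
  out$event_id <- sprintf("%s_e%03d", out$camera_id,
                          stats::ave(seq_len(nrow(out)), out$camera_id, FUN = seq_along))
  dplyr::select(out, "event_id", "camera_id", "start_t", "end_t", "duration_s",
                "n_records", "n_wolves_max", "collar_class", "records")
}

#' Default primary-behaviour precedence
#'
#' When an event contains several coded behaviours, its primary
#' behaviour is the highest-precedence code present. The default ranks
#' fishing outcomes above handling above locomotion, so that an event
#' where a wolf waded and then caught a fish is summarised as a
#' successful fishing attempt, not as wading. The ordering is a package
#' convention and fully configurable.
#'
#' @return character vector, highest precedence first.
#' @export
default_precedence <- function() {
  c("successful_fishing_attempt", "caching_fish", "carrying_fish",
    "failed_fishing_attempt", "unknown_fishing_attempt", "wading",
    "on_creek_bank")
}

#' Assign each event its primary behaviour
#'
#' @param events event tibble from [segment_events()].
#' @param precedence ordered code list, highest precedence first; must be
#'   non-empty and drawn from [ethogram_codes()].
#' @return `events` with a `primary_behaviour` column added.
#' @export
assign_primary_behaviour <- function(events, precedence = default_precedence()) {
  assert_that(length(precedence) > 0, "precedence list must be non-empty",
              "fishwolf_parameter_error")
  assert_that(all(precedence %in% ethogram_codes()),
              "precedence list contains codes outside the ethogram",
              "fishwolf_parameter_error")
  events$primary_behaviour <- vapply(events$records, function(r) {
    present <- precedence[precedence %in% r$behaviour]
    assert_that(length(present) > 0,
                "event contains no behaviour covered by the precedence list",
                "fishwolf_parameter_error")
    present[[1]]
  }, character(1))
  events
}

#' Summarise events: category and collar tallies with integer percentages
#'
#' @param events event tibble with `primary_behaviour` assigned.
#' @return list with `n_events`, `by_category` (tibble of code, n, pct),
#'   `collared` and `uncollared_or_unknown` (each list of n, pct).
#'   Percentages are half-up integer rounded; with zero events they are
#'   absent (`NA`).
#' @export
summarize_events <- function(events) {
  n <- nrow(events)
  primary <- if ("primary_behaviour" %in% names(events))
    events$primary_behaviour else character(0)
  by_cat <- tibble::tibble(behaviour = ethogram_codes())
  counts <- table(factor(primary, levels = ethogram_codes()))
  by_cat$n <- as.integer(counts)
  by_cat$pct <- pct_int(by_cat$n, n)
  n_coll <- sum(events$collar_class == "collared")
  list(
    n_events = n,
    by_category = by_cat,
    collared = list(n = n_coll, pct = pct_int(n_coll, n)),
    uncollared_or_unknown = list(n = n - n_coll, pct = pct_int(n - n_coll, n))
  )
}

#' Tally camera-collar videos by activity
#'
#' Camera-collar footage is coded per video as a fishing `attempt`, the
#' wolf eating or standing `at_fish_kill`, some `other_hunt_eat` activity
#' (hunting or consuming other prey), or `other`. Fishing-behaviour
#' videos are attempts plus at-kill videos; their share of all
#' hunting/eating footage, and (when a grand total is supplied) of all
#' recorded videos, are reported as half-up integer percentages.
#'
#' @param attempts number of fishing-attempt videos.
#' @param at_fish_kill number of videos at a fish kill.
#' @param other_hunt_eat hunting/eating videos not involving fish.
#' @param total_videos optional total number of videos recorded over the
#'   deployment; the all-video share is reported only when given.
#' @return list of tallies and shares.
#' @export
summarize_collar_videos <- function(attempts, at_fish_kill, other_hunt_eat = 0,
                                    total_videos = NULL) {
  fishing <- attempts + at_fish_kill
  hunt_eat <- fishing + other_hunt_eat
  list(
    attempt_videos = attempts,
    at_kill_videos = at_fish_kill,
    fishing_behaviour_videos = fishing,
    hunting_eating_videos = hunt_eat,
    pct_of_hunting_eating = pct_int(fishing, hunt_eat),
    pct_of_all_videos = if (is.null(total_videos)) NA_integer_
                        else pct_int(fishing, total_videos)
  )
}
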