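# Synthetic study system: a collared wolf ranging around a home centre,
# with a spring pulse of nocturnal fishing bouts at a beaver dam on a
# creek, a remote camera on the creek bank, and ground-search annotations
# of the resulting GPS clusters. Everything is deterministic under the
# config seed and carries its own ground truth.

#' Default synthetic creek
#'
#' A gently meandering ~4 km north-south creek centreline on a UTM-style
#' metre grid, with a dam marker at its midpoint vertex.
#'
#' @return a `water_feature` with one dam point.
#' @export
default_creek <- function() {
  yy <- seq(5313000, 5317000, length.out = 41)
  xx <- 500000 + 60 * sin(seq(0, 4 * pi, length.out = 41))
  f <- water_feature("irwin_creek", cbind(xx, yy), name = "Irwin Creek")
  f$dam_points <- matrix(c(xx[[21]], yy[[21]]), ncol = 2)
  f
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a 20-min fix-interval collar
#' followed for 75 days over the spring spawning window (1 April
#' onward, so the span covers a period-length window both before and
#' after the pulse), a 19-day fishing
#' pulse (the observed mean period length) of nocturnal creek-side bouts
#' at a beaver dam, bouts of 1-6 h beginning between 20:00 and 23:00
#' local (inside the 20:00-06:00 night window), a bout probability of
#' 0.8 per schedule night, and a behaviour mixture at the observed
#' seven-category remote-camera frequencies.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param start_date first simulated date.
#' @param n_days days simulated.
#' @param fix_interval_min collar fix spacing in minutes.
#' @param tz local time zone.
#' @param animal_id simulated animal label.
#' @param home_centre planar home-range centre (metres).
#' @param ranging_step_scale mean step length while ranging (m/step).
#' @param ranging_turn_concentration turning-angle concentration
#'   (higher = straighter paths); the turn s.d. is
#'   `1/sqrt(concentration)` radians.
#' @param home_attraction_range distance (m) beyond which the heading is
#'   pulled back toward the home centre.
#' @param creek `water_feature` used as the fishing water source.
#' @param dam_point planar point of the beaver dam (defaults to the
#'   creek's dam marker).
#' @param bout_schedule two dates delimiting the fishing pulse.
#' @param nightly_bout_prob probability a schedule night holds a bout.
#' @param bout_site_jitter s.d. (m) of bout positions around the dam.
#' @param bout_hours min/max bout duration (h).
#' @param bout_start_hours local-hour window in which bouts begin.
#' @param night_window local night hours `c(from, to)`.
#' @param camera_trigger_rate_active camera triggers per hour while a
#'   wolf is in range during a bout.
#' @param behaviour_mixture probability vector over [ethogram_codes()].
#' @param collared_prob probability a camera record shows the collar.
#' @param confounder_fraction fraction of genuine fishing clusters whose
#'   annotation carries a confounder (other-predator sign, or old
#'   remains) that must defeat classification.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       start_date = "2021-04-01",
                       n_days = 75L,
                       fix_interval_min = 20,
                       tz = "America/Chicago",
                       animal_id = "SIM01",
                       home_centre = c(502500, 5315000),
                       ranging_step_scale = 250,
                       ranging_turn_concentration = 2,
                       home_attraction_range = 2000,
                       creek = default_creek(),
                       dam_point = NULL,
                       bout_schedule = c("2021-05-01", "2021-05-19"),
                       nightly_bout_prob = 0.8,
                       bout_site_jitter = 10,
                       bout_hours = c(1, 6),
                       bout_start_hours = c(20, 23),
                       night_window = c(20L, 6L),
                       camera_trigger_rate_active = 20,
                       behaviour_mixture = c(31, 20, 1, 2, 1, 1, 3) / 59,
                       collared_prob = 0.37,
                       confounder_fraction = 0) {
  assert_that(abs(sum(behaviour_mixture) - 1) < 1e-8 &&
                all(behaviour_mixture >= 0) &&
                length(behaviour_mixture) == 7,
              "behaviour_mixture must be 7 non-negative probabilities summing to 1",
              "fishwolf_config_error")
  assert_that(nightly_bout_prob >= 0 && nightly_bout_prob <= 1 &&
                collared_prob >= 0 && collared_prob <= 1 &&
                confounder_fraction >= 0 && confounder_fraction <= 1,
              "probabilities must lie in [0, 1]", "fishwolf_config_error")
  assert_that(bout_site_jitter >= 0, "bout_site_jitter must be >= 0",
              "fishwolf_config_error")
  start_date <- as.Date(start_date)
  sched <- as.Date(bout_schedule)
  assert_that(sched[[1]] >= start_date &&
                sched[[2]] <= start_date + n_days - 1,
              "bout_schedule must lie inside the simulated span",
              "fishwolf_config_error")
  cfg <- list(seed = as.integer(seed), start_date = start_date,
              n_days = as.integer(n_days), fix_interval_min = fix_interval_min,
              tz = tz, animal_id = animal_id, home_centre = home_centre,
              ranging_step_scale = ranging_step_scale,
              ranging_turn_concentration = ranging_turn_concentration,
              home_attraction_range = home_attraction_range,
              creek = creek,
              dam_point = dam_point %||% creek$dam_points[1, ],
              bout_schedule = sched,
              nightly_bout_prob = nightly_bout_prob,
              bout_site_jitter = bout_site_jitter,
              bout_hours = bout_hours, bout_start_hours = bout_start_hours,
              night_window = night_window,
              camera_trigger_rate_active = camera_trigger_rate_active,
              behaviour_mixture = behaviour_mixture,
              collared_prob = collared_prob,
              confounder_fraction = confounder_fraction)
  class(cfg) <- "sim_config"
  cfg
}

# draw the realised bout intervals for the schedule nights
draw_bouts <- function(config) {
  dates <- seq(config$bout_schedule[[1]], config$bout_schedule[[2]], by = "day")
  has_bout <- runif(length(dates)) < config$nightly_bout_prob
  dates <- dates[has_bout]
  if (length(dates) == 0) {
    return(tibble::tibble(date = as.Date(character(0)),
                          start = as.POSIXct(character(0)),
                          end = as.POSIXct(character(0))))
  }
  start_h <- runif(length(dates), config$bout_start_hours[[1]],
                   config$bout_start_hours[[2]])
  dur_h <- runif(length(dates), config$bout_hours[[1]], config$bout_hours[[2]])
  start <- lubridate::force_tz(as.POSIXct(dates) + start_h * 3600, config$tz)
  tibble::tibble(date = dates, start = start, end = start + dur_h * 3600)
}

#' Simulate a two-state wolf trajectory with known ground truth
#'
#' State RANGING is a correlated random walk whose heading is pulled
#' back toward the home centre once the animal strays beyond the
#' attraction range; state FISHING-BOUT places fixes within
#' `bout_site_jitter` metres of the dam point for the duration of each
#' realised nocturnal bout. The sampler is the collar: positions are
#' recorded on the fix-interval grid only.
#'
#' @param config a [sim_config()].
#' @return list with `trajectory` (an `fw_trajectory`) and `truth`
#'   (list: `bouts` tibble with date/start/end, `true_period` —
#'   first/last realised bout dates, `NULL` when no bouts).
#' @export
simulate_trajectory <- function(config) {
  withr::with_seed(config$seed, {
    bouts <- draw_bouts(config)
    t0 <- lubridate::force_tz(as.POSIXct(config$start_date), config$tz)
    n <- config$n_days * as.integer(24 * 60 / config$fix_interval_min)
    times <- t0 + (seq_len(n) - 1) * config$fix_interval_min * 60
    tn <- as.numeric(times)
    in_bout <- rep(FALSE, n)
    for (k in seq_len(nrow(bouts))) {
      in_bout <- in_bout | (tn >= as.numeric(bouts$start[[k]]) &
                            tn <= as.numeric(bouts$end[[k]]))
    }
    x <- numeric(n); y <- numeric(n)
    pos <- config$home_centre
    heading <- runif(1, 0, 2 * pi)
    sd_turn <- 1 / sqrt(config$ranging_turn_concentration)
    for (i in seq_len(n)) {
      if (in_bout[[i]]) {
        pos <- config$dam_point + rnorm(2, 0, config$bout_site_jitter)
        heading <- runif(1, 0, 2 * pi)
      } else {
        dvec <- config$home_centre - pos
        d <- sqrt(sum(dvec^2))
        w <- stats::plogis((d - config$home_attraction_range) /
                             (config$home_attraction_range / 4))
        hx <- (1 - w) * cos(heading) + w * dvec[[1]] / max(d, 1)
        hy <- (1 - w) * sin(heading) + w * dvec[[2]] / max(d, 1)
        heading <- atan2(hy, hx) + rnorm(1, 0, sd_turn)
        step <- stats::rgamma(1, shape = 2, scale = config$ranging_step_scale / 2)
        pos <- pos + step * c(cos(heading), sin(heading))
      }
      x[[i]] <- pos[[1]]; y[[i]] <- pos[[2]]
    }
    traj <- trajectory(config$animal_id, times, x, y, config$fix_interval_min)
    truth <- list(
      bouts = bouts,
      true_period = if (nrow(bouts) > 0) c(min(bouts$date), max(bouts$date)) else NULL
    )
    list(trajectory = traj, truth = truth)
  })
}

#' Simulate camera-trap records at the dam during true bouts
#'
#' The camera sits on the creek bank at the dam. While a bout is under
#' way it triggers as a memoryless (Poisson) arrival process at
#' `camera_trigger_rate_active` per hour; each record draws a behaviour
#' code from the configured mixture and a collar status. The true event
#' partition under the 10-minute gap rule is computed directly from the
#' arrival times and returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_trajectory()].
#' @param camera_id camera label.
#' @return list with `records` (camera-record tibble) and
#'   `true_event_partition` (integer event index per sorted record).
#' @export
simulate_camera_records <- function(config, truth, camera_id = "CAM01") {
  withr::with_seed(config$seed + 1L, {
    bouts <- truth$bouts
    if (config$camera_trigger_rate_active <= 0) {
      if (nrow(bouts) > 0) rlang::warn("zero trigger rate with bouts present; no records")
      empty <- camera_records(character(0), as.POSIXct(character(0), tz = config$tz),
                              character(0), integer(0), character(0),
                              character(0), character(0))
      return(list(records = empty, true_event_partition = integer(0)))
    }
    times <- list()
    for (k in seq_len(nrow(bouts))) {
      tt <- as.numeric(bouts$start[[k]])
      end <- as.numeric(bouts$end[[k]])
      repeat {
        tt <- tt + rexp(1, rate = config$camera_trigger_rate_active / 3600)
        if (tt > end) break
        times[[length(times) + 1]] <- tt
      }
    }
    if (length(times) == 0) {
      empty <- camera_records(character(0), as.POSIXct(character(0), tz = config$tz),
                              character(0), integer(0), character(0),
                              character(0), character(0))
      return(list(records = empty, true_event_partition = integer(0)))
    }
    tt <- sort(unlist(times))
    t <- as.POSIXct(tt, origin = "1970-01-01", tz = config$tz)
    m <- length(tt)
    collared <- runif(m) < config$collared_prob
    recs <- camera_records(
      camera_id = camera_id, t = t, media = "video", n_wolves = 1L,
      collar_status = ifelse(collared, "collared",
                             sample(c("uncollared", "unknown"), m, replace = TRUE)),
      wolf_id = ifelse(collared, config$animal_id, NA_character_),
      behaviour = sample(ethogram_codes(), m, replace = TRUE,
                         prob = config$behaviour_mixture)
    )
    # true partition, straight from the rule's definition on arrival times
    partition <- cumsum(c(TRUE, diff(sort(tt)) / 60 > 10))
    list(records = recs, true_event_partition = partition)
  })
}

#' Simulate ground-search annotations for detected clusters
#'
#' Clusters that overlap a true bout in time and sit at the dam in space
#' receive fresh fish remains and abundant wolf sign; a configured
#' fraction of those additionally receive a confounder (other-predator
#' sign, or old-not-fresh remains) so the exclusion rules are exercised.
#' All other clusters are annotated as ordinary (non-fishing) sites.
#'
#' @param clusters cluster tibble from [detect_clusters()].
#' @param truth ground truth from [simulate_trajectory()].
#' @param config a [sim_config()].
#' @param site_radius metres around the dam within which a cluster
#'   centroid counts as at-the-site (default 100).
#' @return list with `annotations` (tibble), `true_ids` (clusters truly
#'   at fishing bouts) and `confounded_ids` (subset given confounders;
#'   expected classified positives are `setdiff(true_ids, confounded_ids)`).
#' @export
simulate_annotations <- function(clusters, truth, config, site_radius = 100) {
  withr::with_seed(config$seed + 2L, {
    n <- nrow(clusters)
    bouts <- truth$bouts
    at_site <- rep(FALSE, n)
    if (n > 0) {
      d <- sqrt((clusters$centroid_x - config$dam_point[[1]])^2 +
                  (clusters$centroid_y - config$dam_point[[2]])^2)
      overlap <- rep(FALSE, n)
      for (k in seq_len(nrow(bouts))) {
        overlap <- overlap | (as.numeric(clusters$start_t) <= as.numeric(bouts$end[[k]]) &
                              as.numeric(clusters$end_t) >= as.numeric(bouts$start[[k]]))
      }
      at_site <- overlap & d <= site_radius
    }
    confound <- at_site & runif(n) < config$confounder_fraction
    other_pred <- confound & runif(n) < 0.5
    old <- confound & !other_pred
    ann <- tibble::tibble(
      cluster_id = clusters$cluster_id,
      fresh_fish_remains = at_site & !old,
      wolf_sign_abundant = at_site,
      other_predator_sign = other_pred,
      remains_old = old,
      fish_species = ifelse(at_site & !confound, "white_sucker", NA_character_),
      water_depth_class = ifelse(at_site, "lt_1m", "unknown"),
      active_beaver_dam_nearby = at_site
    )
    list(annotations = ann,
         true_ids = clusters$cluster_id[at_site],
         confounded_ids = clusters$cluster_id[confound])
  })
}
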