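#' Infer a fishing period from pooled evidence
#'
#' The fishing period of an animal-year runs from the first to the last
#' date the animal was documented fishing by any evidence source (GPS
#' clusters, remote cameras, camera collar, field observation). Its
#' length is counted inclusively of both endpoint dates, so a period
#' from 12 to 18 May is 7 days. With no dated evidence the result is an
#' absence (a zero-row tibble), never a zero-length period.
#'
#' @param evidence evidence tibble (`animal_id`, `date`, `source`, ...).
#' @param animal_id animal to summarise.
#' @param year calendar year; defaults to the year of the evidence.
#' @return one-row tibble (`animal_id`, `year`, `start_date`, `end_date`,
#'   `length_days`, `defining_source`), or zero rows when no dated
#'   evidence exists.
#' @export
infer_fishing_period <- function(evidence, animal_id, year = NULL) {
  ev <- evidence[evidence$animal_id == animal_id & !is.na(evidence$date), ]
  if (!is.null(year)) ev <- ev[lubridate::year(ev$date) == year, ]
  if (nrow(ev) == 0) return(empty_periods())
  start <- min(ev$date); end <- max(ev$date)
  src <- paste(sort(unique(ev$source)), collapse = "+")
  tibble::tibble(animal_id = animal_id,
                 year = lubridate::year(start),
                 start_date = start, end_date = end,
                 length_days = inclusive_days(start, end),
                 defining_source = src)
}

empty_periods <- function() {
  tibble::tibble(animal_id = character(0), year = integer(0),
                 start_date = as.Date(character(0)), end_date = as.Date(character(0)),
                 length_days = integer(0), defining_source = character(0))
}

#' Infer fishing periods for every animal-year in an evidence table
#' @inheritParams infer_fishing_period
#' @return period tibble, one row per animal-year with dated evidence.
#' @export
infer_all_periods <- function(evidence) {
  ev <- evidence[!is.na(evidence$date), ]
  if (nrow(ev) == 0) return(empty_periods())
  keys <- unique(tibble::tibble(animal_id = ev$animal_id,
                                year = lubridate::year(ev$date)))
  purrr::pmap_dfr(keys, function(animal_id, year) {
    infer_fishing_period(ev, animal_id, year)
  })
}

#' Summarise fishing-period lengths
#'
#' Reports the arithmetic mean, the sample (n-1) and population (n)
#' standard deviations, and the maximum of the period lengths. Both s.d.
#' conventions are reported because summaries in the source literature
#' do not always state which was used; with a single period the s.d. is
#' absent (`NA`).
#'
#' @param periods period tibble (see [infer_fishing_period()]).
#' @return list with `n`, `mean_days`, `sd_sample`, `sd_population`,
#'   `max_days`; `NULL` for an empty input.
#' @export
summarize_periods <- function(periods) {
  len <- periods$length_days
  if (length(len) == 0) return(NULL)
  list(
    n = length(len),
    mean_days = mean(len),
    sd_sample = if (length(len) > 1) stats::sd(len) else NA_real_,
    sd_population = if (length(len) > 1)
      sqrt(mean((len - mean(len))^2)) else NA_real_,
    max_days = max(len)
  )
}

# ---- geometry ---------------------------------------------------------------

# minimum Euclidean distance from points (px, py) to a polyline given as
# an n x 2 vertex matrix; vectorised over points
dist_point_polyline <- function(px, py, vertices) {
  assert_that(is.matrix(vertices) && nrow(vertices) >= 2,
              "polyline needs at least 2 vertices", "fishwolf_geometry_error")
  ax <- vertices[-nrow(vertices), 1]; ay <- vertices[-nrow(vertices), 2]
  bx <- vertices[-1, 1]; by <- vertices[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  best <- rep(Inf, length(px))
  for (s in seq_along(ax)) {
    tt <- ((px - ax[[s]]) * dx[[s]] + (py - ay[[s]]) * dy[[s]]) / len2[[s]]
    tt <- pmin(1, pmax(0, tt))
    d2 <- (px - (ax[[s]] + tt * dx[[s]]))^2 + (py - (ay[[s]] + tt * dy[[s]]))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Distance from a point to a water feature
#'
#' Minimum Euclidean point-to-segment distance (metres) over all
#' segments of the feature's centreline polyline.
#'
#' @param x,y planar point coordinates (vectorised).
#' @param feature a `water_feature`.
#' @return numeric vector of distances in metres.
#' @export
distance_to_feature <- function(x, y, feature) {
  assert_that(inherits(feature, "water_feature"),
              "feature must be a water_feature", "fishwolf_geometry_error")
  dist_point_polyline(x, y, feature$vertices)
}

# ---- buffer occupancy -------------------------------------------------------

#' Buffer-occupancy profile of a trajectory around a water feature
#'
#' Each GPS fix inside the buffer contributes its full nominal fix
#' interval of time — an index of occupancy, not an interpolation.
#' `hours_per_day` is total in-buffer time divided by the number of
#' calendar days in the window (inclusive). Hour-of-day and per-date
#' histograms of in-buffer fixes are returned for activity profiling.
#'
#' @param traj an `fw_trajectory` with a uniform nominal interval.
#' @param feature a `water_feature`.
#' @param radius buffer radius in metres (20 = actively hunting,
#'   500 = hunting plus handling, by convention).
#' @param window two Dates (start, end) delimiting the profile window.
#' @param phase label stored on the profile (`before`/`during`/`after`
#'   or freeform).
#' @param tz local time zone for calendar dates and hours.
#' @return an `occupancy_profile` list: identifiers, window, `n_days`,
#'   `n_fixes_in`, `hours_total`, `hours_per_day`, `by_hour` (named
#'   24-vector of in-buffer fix counts), `by_date` (tibble date, n).
#' @export
buffer_occupancy <- function(traj, feature, radius, window,
                             phase = "during", tz = "America/Chicago") {
  assert_that(length(unique(traj$interval_min)) == 1,
              "trajectory must have a uniform nominal fix interval within the window",
              "fishwolf_precondition_error")
  window <- as.Date(window)
  dates <- as.Date(traj$t, tz = tz)
  span <- range(dates)
  if (window[[2]] < span[[1]] || window[[1]] > span[[2]]) {
    rlang::warn("profile window lies outside the trajectory span; empty profile")
  }
  in_win <- dates >= window[[1]] & dates <= window[[2]]
  sub <- traj[in_win, ]
  d <- if (nrow(sub) > 0) distance_to_feature(sub$x, sub$y, feature) else numeric(0)
  inside <- d <= radius
  n_in <- sum(inside)
  interval_min <- traj$interval_min[[1]]
  n_days <- inclusive_days(window[[1]], window[[2]])
  hours_total <- n_in * interval_min / 60
  hrs <- lubridate::hour(lubridate::with_tz(sub$t[inside], tz))
  by_hour <- stats::setNames(tabulate(hrs + 1L, nbins = 24L), sprintf("%02d", 0:23))
  bd <- table(as.Date(sub$t[inside], tz = tz))
  by_date <- tibble::tibble(date = as.Date(names(bd)), n = as.integer(bd))
  structure(list(
    animal_id = traj$animal_id[[1]], feature_id = feature$feature_id,
    radius = radius, phase = phase, window = window, n_days = n_days,
    n_fixes_in = n_in, hours_total = hours_total,
    hours_per_day = hours_total / n_days,
    by_hour = by_hour, by_date = by_date
  ), class = "occupancy_profile")
}

#' Before/during/after occupancy comparison around a fishing period
#'
#' The before window is the stretch of calendar days of the same length
#' as the fishing period immediately preceding its start; the after
#' window immediately follows its end. The three windows are disjoint
#' and contiguous. A phase whose window is not fully covered by the
#' trajectory's date span is reported absent (`NA` hours), not zero.
#'
#' @param traj an `fw_trajectory` (20-min collar expected for these
#'   indices).
#' @param feature a `water_feature`.
#' @param period one-row period tibble.
#' @param radii buffer radii in metres (default 20 and 500).
#' @param tz local time zone.
#' @return list with `summary` (tibble phase x radius with
#'   `hours_per_day`) and `profiles` (named list of `occupancy_profile`s
#'   keyed `phase_radius`, absent phases omitted).
#' @export
phase_comparison <- function(traj, feature, period, radii = c(20, 500),
                             tz = "America/Chicago") {
  assert_that(nrow(period) == 1, "period must be a single row",
              "fishwolf_parameter_error")
  len <- period$length_days[[1]]
  windows <- list(
    before = c(period$start_date[[1]] - len, period$start_date[[1]] - 1),
    during = c(period$start_date[[1]], period$end_date[[1]]),
    after  = c(period$end_date[[1]] + 1, period$end_date[[1]] + len)
  )
  span <- range(as.Date(traj$t, tz = tz))
  profiles <- list()
  rows <- list()
  for (ph in names(windows)) {
    w <- windows[[ph]]
    covered <- w[[1]] >= span[[1]] && w[[2]] <= span[[2]]
    for (r in radii) {
      if (covered) {
        p <- buffer_occupancy(traj, feature, r, w, phase = ph, tz = tz)
        profiles[[sprintf("%s_%g", ph, r)]] <- p
        hpd <- p$hours_per_day
      } else {
        hpd <- NA_real_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        animal_id = traj$animal_id[[1]], phase = ph, radius = r,
        window_start = w[[1]], window_end = w[[2]], covered = covered,
        hours_per_day = hpd)
    }
  }
  list(summary = dplyr::bind_rows(rows), profiles = profiles)
}

#' Pooled hourly/seasonal activity profiles and nocturnality
#'
#' Pools in-buffer fix counts across occupancy profiles into an
#' hour-of-day histogram and a per-date (seasonal) histogram, and
#' computes the night share: the fraction of in-buffer fixes whose local
#' hour falls in the night window (default 20:00-06:00).
#'
#' @param profiles list of `occupancy_profile` objects.
#' @param night_window integer hours `c(from, to)`; the window wraps
#'   midnight when `from > to`.
#' @return list with `by_hour` (named 24-vector), `by_date` (tibble),
#'   `n_fixes`, `night_share` (`NA` when no in-buffer fixes).
#' @export
activity_profiles <- function(profiles, night_window = c(20L, 6L)) {
  assert_that(length(profiles) >= 1, "at least one profile required",
              "fishwolf_parameter_error")
  by_hour <- Reduce(`+`, lapply(profiles, function(p) p$by_hour))
  by_date <- dplyr::bind_rows(lapply(profiles, function(p) p$by_date))
  by_date <- dplyr::summarise(dplyr::group_by(by_date, .data$date),
                              n = sum(.data$n), .groups = "drop")
  total <- sum(by_hour)
  night <- sum(by_hour[is_night_hour(0:23, night_window)])
  list(by_hour = by_hour, by_date = by_date, n_fixes = total,
       night_share = if (total > 0) night / total else NA_real_)
}
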