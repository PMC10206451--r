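test_that("fishing periods are inclusive date spans of pooled evidence", {
  ev <- tibble::tibble(
    animal_id = c("V062", "V062", "V062", "O0C", "O0C"),
    date = as.Date(c("2018-05-09", "2018-05-14", "2018-05-25",
                     "2021-05-26", "2021-07-07")),
    source = c("cluster", "cluster", "cluster", "cluster", "cluster"))
  p <- infer_fishing_period(ev, "V062")
  expect_equal(p$start_date, as.Date("2018-05-09"))
  expect_equal(p$end_date, as.Date("2018-05-25"))
  expect_equal(p$length_days, 17L)
  expect_equal(infer_fishing_period(ev, "O0C")$length_days, 43L)
  # a single evidence date is a one-day period
  single <- tibble::tibble(animal_id = "W", date = as.Date("2020-05-20"),
                           source = "camera_collar")
  expect_equal(infer_fishing_period(single, "W")$length_days, 1L)
  # no dated evidence: an absence, not a zero-length period
  expect_equal(nrow(infer_fishing_period(ev, "V067")), 0)
  none <- tibble::tibble(animal_id = "W", date = as.Date(NA), source = "cluster")
  expect_equal(nrow(infer_fishing_period(none, "W")), 0)
})

test_that("inclusive day-count law: length = delta-days + 1", {
  withr::with_seed(77, {
    starts <- as.Date("2019-01-01") + sample(0:400, 50, replace = TRUE)
    ends <- starts + sample(0:60, 50, replace = TRUE)
    for (i in seq_along(starts)) {
      ev <- tibble::tibble(animal_id = "W", date = c(starts[[i]], ends[[i]]),
                           source = "cluster")
      p <- infer_fishing_period(ev, "W")
      expect_equal(p$length_days, as.integer(ends[[i]] - starts[[i]]) + 1L)
    }
  })
})

test_that("period summaries match a two-pass reference computation", {
  lens <- c(31L, 28L, 7L, 17L, 10L, 18L, 23L, 11L, 9L, 24L, 8L, 43L)
  p <- tibble::tibble(animal_id = sprintf("W%02d", seq_along(lens)),
                      year = 2020L, start_date = as.Date("2020-05-01"),
                      end_date = as.Date("2020-05-01") + lens - 1,
                      length_days = lens, defining_source = "cluster")
  s <- summarize_periods(p)
  # independent two-pass mean and variance
  m_ref <- sum(lens) / length(lens)
  var_ref <- sum((lens - m_ref)^2) / (length(lens) - 1)
  expect_equal(s$mean_days, m_ref)
  expect_equal(s$sd_sample, sqrt(var_ref))
  expect_equal(s$sd_population, sqrt(var_ref * (length(lens) - 1) / length(lens)))
  expect_equal(s$max_days, 43L)
  # single period: mean is the value, sd absent
  s1 <- summarize_periods(p[1, ])
  expect_equal(s1$mean_days, 31)
  expect_true(is.na(s1$sd_sample))
  expect_null(summarize_periods(p[0, ]))
})

test_that("point-to-polyline distance is exact on knowns and vs dense sampling", {
  creek <- straight_creek()
  expect_equal(distance_to_feature(0, 500, creek), 0)
  expect_equal(distance_to_feature(100, 500, creek), 100)
  # beyond an endpoint the nearest point is the endpoint itself
  expect_equal(distance_to_feature(30, 1040, creek), 50)

  bend <- water_feature("bend", cbind(c(0, 100, 100), c(0, 0, 80)))
  withr::with_seed(88, {
    px <- runif(100, -50, 150); py <- runif(100, -50, 130)
    d <- distance_to_feature(px, py, bend)
    # dense vertex-sampling oracle: points every 0.1 m along the line
    samp <- rbind(cbind(seq(0, 100, by = 0.1), 0),
                  cbind(100, seq(0, 80, by = 0.1)))
    d_ref <- vapply(seq_along(px), function(i) {
      sqrt(min((samp[, 1] - px[[i]])^2 + (samp[, 2] - py[[i]])^2))
    }, numeric(1))
    expect_lt(max(abs(d - d_ref)), 0.5)
  })
})

test_that("buffer occupancy weights each in-buffer fix by its interval", {
  creek <- straight_creek()
  day <- as.Date("2021-05-01")
  # all 72 fixes of a 20-min day inside the buffer -> 24 h that day
  tr <- make_traj(x = rep(5, 72), y = rep(500, 72))
  prof <- buffer_occupancy(tr, creek, radius = 20, window = c(day, day),
                           tz = LOCAL_TZ)
  expect_equal(prof$hours_per_day, 24)
  expect_equal(prof$n_fixes_in, 72)
  # conservation: histograms total the in-buffer fix count
  expect_equal(sum(prof$by_hour), prof$n_fixes_in)
  expect_equal(sum(prof$by_date$n), prof$n_fixes_in)

  # no fixes in buffer -> 0 h
  far <- make_traj(x = rep(5000, 72), y = rep(0, 72))
  expect_equal(buffer_occupancy(far, creek, 20, c(day, day), tz = LOCAL_TZ)$hours_per_day, 0)

  # mixed fixture equals a brute-force sum with an independent distance flag
  withr::with_seed(99, {
    tr2 <- random_walk_traj(600, step_sd = 150)
    win <- range(as.Date(tr2$t, tz = LOCAL_TZ))
    for (r in c(20, 500)) {
      prof2 <- buffer_occupancy(tr2, creek, r, win, tz = LOCAL_TZ)
      inside <- vapply(seq_len(nrow(tr2)), function(i) {
        # scalar point-segment distance, written out independently
        ax <- 0; ay <- 0; bx <- 0; by <- 1000
        tt <- max(0, min(1, ((tr2$x[[i]] - ax) * (bx - ax) +
                               (tr2$y[[i]] - ay) * (by - ay)) / 1000^2))
        sqrt((tr2$x[[i]] - (ax + tt * (bx - ax)))^2 +
               (tr2$y[[i]] - (ay + tt * (by - ay)))^2) <= r
      }, logical(1))
      expect_equal(prof2$hours_total, sum(inside) * 20 / 60)
    }
  })

  # a window outside the trajectory span warns and is empty
  expect_warning(
    empty <- buffer_occupancy(tr, creek, 20, c(day + 400, day + 401), tz = LOCAL_TZ),
    "outside")
  expect_equal(empty$n_fixes_in, 0)
})

test_that("phase windows are adjacent, equal length, and nested across radii", {
  creek <- straight_creek()
  # 30 simulated days; fishing period days 11-20; in-buffer only during
  t0 <- as.POSIXct("2021-05-01 00:00:00", tz = LOCAL_TZ)
  n <- 30 * 72
  t <- t0 + (seq_len(n) - 1) * 20 * 60
  dates <- as.Date(t, tz = LOCAL_TZ)
  period_days <- as.Date("2021-05-11") + 0:9
  inside <- dates %in% period_days
  x <- ifelse(inside, 5, 3000)
  tr <- trajectory("W1", t, x, rep(500, n), 20)
  period <- tibble::tibble(animal_id = "W1", year = 2021L,
                           start_date = min(period_days), end_date = max(period_days),
                           length_days = 10L, defining_source = "cluster")
  pc <- phase_comparison(tr, creek, period, tz = LOCAL_TZ)
  s <- pc$summary
  # windows: disjoint, contiguous with the period, equal length
  b <- s[s$phase == "before", ][1, ]
  a <- s[s$phase == "after", ][1, ]
  expect_equal(b$window_end, period$start_date - 1)
  expect_equal(a$window_start, period$end_date + 1)
  expect_equal(as.integer(b$window_end - b$window_start),
               as.integer(a$window_end - a$window_start))
  # in-buffer only inside the period
  expect_equal(s$hours_per_day[s$phase == "before"], c(0, 0))
  expect_equal(s$hours_per_day[s$phase == "after"], c(0, 0))
  expect_true(all(s$hours_per_day[s$phase == "during"] > 0))
  # nesting: 500 m hours >= 20 m hours in every phase
  for (ph in unique(s$phase)) {
    expect_gte(s$hours_per_day[s$phase == ph & s$radius == 500],
               s$hours_per_day[s$phase == ph & s$radius == 20])
  }

  # an uncovered phase window is absent, not zero
  late <- tibble::tibble(animal_id = "W1", year = 2021L,
                         start_date = as.Date("2021-05-25"),
                         end_date = as.Date("2021-05-30"),
                         length_days = 6L, defining_source = "cluster")
  pc2 <- phase_comparison(tr, creek, late, tz = LOCAL_TZ)
  expect_true(all(is.na(pc2$summary$hours_per_day[pc2$summary$phase == "after"])))
  expect_false(any(pc2$summary$covered[pc2$summary$phase == "after"]))
})

test_that("activity profiles pool histograms and measure nocturnality", {
  creek <- straight_creek()
  day <- as.Date("2021-05-01")
  t0 <- as.POSIXct("2021-05-01 00:00:00", tz = LOCAL_TZ)
  # fixes at 21:00 and 03:00 only -> night share 1
  tr <- trajectory("W1", t0 + c(3, 21) * 3600, c(5, 5), c(500, 500), 20)
  prof <- buffer_occupancy(tr, creek, 20, c(day, day), tz = LOCAL_TZ)
  ap <- activity_profiles(list(prof))
  expect_equal(ap$night_share, 1.0)

  # uniform hourly fixes -> night share = 10/24
  tru <- trajectory("W2", t0 + (0:23) * 3600, rep(5, 24), rep(500, 24), 60)
  profu <- buffer_occupancy(tru, creek, 20, c(day, day), tz = LOCAL_TZ)
  apu <- activity_profiles(list(profu))
  expect_equal(apu$night_share, 10 / 24)
  # pooling conserves counts
  both <- activity_profiles(list(prof, profu))
  expect_equal(both$n_fixes, 26)
  expect_equal(sum(both$by_date$n), 26)
})
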