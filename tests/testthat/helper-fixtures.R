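# Shared fixtures and independent oracles, built in code at test time.

LOCAL_TZ <- "America/Chicago"

`%||%` <- function(a, b) if (is.null(a)) b else a

# a trajectory with fixes at given coordinates, regular 20-min spacing
make_traj <- function(x, y, interval_min = 20, animal_id = "W1",
                      t0 = as.POSIXct("2021-05-01 00:00:00", tz = LOCAL_TZ),
                      t = NULL) {
  t <- t %||% (t0 + (seq_along(x) - 1) * interval_min * 60)
  trajectory(animal_id, t, x, y, interval_min)
}

# an unconstrained random walk trajectory for oracle comparisons
random_walk_traj <- function(n, step_sd = 120, interval_min = 20,
                             gap_dropout = 0) {
  x <- cumsum(rnorm(n, 0, step_sd))
  y <- cumsum(rnorm(n, 0, step_sd))
  t0 <- as.POSIXct("2021-05-01 00:00:00", tz = LOCAL_TZ)
  steps <- rep(1, n)
  if (gap_dropout > 0) {
    # occasional missed fixes: some inter-fix gaps are several intervals
    steps <- 1 + stats::rbinom(n, 8, gap_dropout)
  }
  t <- t0 + cumsum(steps) * interval_min * 60
  make_traj(x, y, interval_min, t = t)
}

# Reference cluster enumeration straight from the definition: a cluster
# is >= min_fixes consecutive fixes all within `radius` of the cluster's
# first fix, with consecutive members no further apart in time than
# max_gap_min; clusters are taken disjointly, left to right. Uses a full
# pairwise distance matrix rather than the scan's incremental test.
oracle_clusters <- function(traj, radius = 200, min_fixes = 2,
                            max_gap_min = NULL) {
  n <- nrow(traj)
  max_gap_min <- max_gap_min %||% (3 * traj$interval_min[[1]])
  D <- as.matrix(stats::dist(cbind(traj$x, traj$y)))
  gap <- c(NA, diff(as.numeric(traj$t)) / 60)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && D[j + 1, i] <= radius && gap[[j + 1]] <= max_gap_min) {
      j <- j + 1
    }
    if (j - i + 1 >= min_fixes) {
      out <- rbind(out, c(first = i, last = j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# camera records spaced so that each record is its own event
make_singleton_event_records <- function(behaviours, collar_status = "unknown",
                                         camera_id = "CAM01") {
  n <- length(behaviours)
  t0 <- as.POSIXct("2018-05-07 06:00:00", tz = LOCAL_TZ)
  camera_records(camera_id = camera_id, t = t0 + (seq_len(n) - 1) * 3600,
                 media = "video", n_wolves = 1L,
                 collar_status = rep_len(collar_status, n),
                 behaviour = behaviours)
}

# the 59-event remote-camera fixture: categories and collar tallies as
# tallied in the field seasons the package emulates
event_fixture_59 <- function() {
  counts <- c(successful_fishing_attempt = 1, failed_fishing_attempt = 2,
              unknown_fishing_attempt = 1, caching_fish = 3, carrying_fish = 1,
              wading = 20, on_creek_bank = 31)
  behaviours <- rep(names(counts), counts)
  collar <- c(rep("collared", 22), rep("uncollared", 25), rep("unknown", 12))
  make_singleton_event_records(behaviours, collar_status = collar)
}

# small straight creek for geometry tests: a 1 km vertical line at x = 0
straight_creek <- function() {
  water_feature("test_creek", cbind(c(0, 0), c(0, 1000)))
}
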