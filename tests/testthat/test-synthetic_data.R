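test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 42, start_date = "2021-04-15", n_days = 20,
                    bout_schedule = c("2021-04-20", "2021-04-30"))
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$truth$bouts, b$truth$bouts)
  ca <- simulate_camera_records(cfg, a$truth)
  cb <- simulate_camera_records(cfg, b$truth)
  expect_identical(ca$records, ca$records[order(ca$records$t), ])
  expect_identical(ca, cb)
  # a different seed produces a different stream
  other <- simulate_trajectory(sim_config(seed = 43, start_date = "2021-04-15", n_days = 20,
                                          bout_schedule = c("2021-04-20", "2021-04-30")))
  expect_false(identical(a$trajectory$x, other$trajectory$x))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(behaviour_mixture = rep(1, 7)),
               class = "fishwolf_config_error")
  expect_error(sim_config(nightly_bout_prob = 1.5), class = "fishwolf_config_error")
  expect_error(sim_config(n_days = 10, bout_schedule = c("2021-05-01", "2021-05-19")),
               class = "fishwolf_config_error")
})

test_that("no bouts means no fishing signal at the creek", {
  cfg <- sim_config(seed = 5, start_date = "2021-04-15", n_days = 30, nightly_bout_prob = 0,
                    bout_schedule = c("2021-04-20", "2021-05-10"))
  sim <- simulate_trajectory(cfg)
  expect_equal(nrow(sim$truth$bouts), 0)
  expect_null(sim$truth$true_period)
  # no fix within 20 m of the dam
  d <- sqrt((sim$trajectory$x - cfg$dam_point[[1]])^2 +
              (sim$trajectory$y - cfg$dam_point[[2]])^2)
  expect_equal(sum(d <= 20), 0)
  cl <- detect_clusters(sim$trajectory)
  ann <- simulate_annotations(cl, sim$truth, cfg)
  expect_equal(sum(is_fishing_cluster(ann$annotations)), 0)
})

test_that("certain nightly bouts with tight jitter give exact period recovery", {
  cfg <- sim_config(seed = 9, start_date = "2021-04-15", n_days = 40, nightly_bout_prob = 1,
                    bout_site_jitter = 5,
                    bout_schedule = c("2021-04-25", "2021-05-05"))
  sim <- simulate_trajectory(cfg)
  expect_equal(nrow(sim$truth$bouts), 11)
  expect_equal(sim$truth$true_period, cfg$bout_schedule)
  cl <- detect_clusters(sim$trajectory)
  ann <- simulate_annotations(cl, sim$truth, cfg)
  ev <- fishing_evidence_from_clusters(cl, ann$annotations,
                                       list(irwin_creek = cfg$creek), tz = cfg$tz)
  p <- infer_fishing_period(ev, cfg$animal_id)
  expect_equal(p$start_date, cfg$bout_schedule[[1]])
  expect_equal(p$end_date, cfg$bout_schedule[[2]])
})

test_that("camera records obey the configured bout structure", {
  cfg <- sim_config(seed = 13, start_date = "2021-04-15", n_days = 30,
                    bout_schedule = c("2021-04-20", "2021-05-10"),
                    camera_trigger_rate_active = 60)
  sim <- simulate_trajectory(cfg)
  cam <- simulate_camera_records(cfg, sim$truth)
  expect_gt(nrow(cam$records), 0)
  # records only during true bouts
  tn <- as.numeric(cam$records$t)
  in_bout <- rep(FALSE, length(tn))
  for (k in seq_len(nrow(sim$truth$bouts))) {
    in_bout <- in_bout | (tn >= as.numeric(sim$truth$bouts$start[[k]]) &
                            tn <= as.numeric(sim$truth$bouts$end[[k]]))
  }
  expect_true(all(in_bout))
  # two bouts a night apart are always separate events
  ev <- segment_events(cam$records)
  expect_gte(nrow(ev), nrow(sim$truth$bouts))
  # the stored true partition matches the gap rule re-applied
  pred <- cumsum(c(TRUE, diff(as.numeric(sort(cam$records$t))) / 60 > 10))
  expect_equal(pred, cam$true_event_partition)

  # zero trigger rate: warning and empty output
  cfg0 <- sim_config(seed = 13, start_date = "2021-04-15", n_days = 30,
                     bout_schedule = c("2021-04-20", "2021-05-10"),
                     camera_trigger_rate_active = 0)
  expect_warning(cam0 <- simulate_camera_records(cfg0, sim$truth), "zero")
  expect_equal(nrow(cam0$records), 0)
})

test_that("behaviour mixture is recovered from large singleton-event samples", {
  withr::with_seed(21, {
    mixture <- c(31, 20, 1, 2, 1, 1, 3) / 59
    names(mixture) <- ethogram_codes()
    n <- 5000
    codes <- sample(ethogram_codes(), n, replace = TRUE, prob = mixture)
    ev <- assign_primary_behaviour(segment_events(make_singleton_event_records(codes)))
    s <- summarize_events(ev)
    got <- setNames(s$by_category$n / s$n_events, s$by_category$behaviour)
    # within ~4 binomial standard errors of the target shares
    for (code in ethogram_codes()) {
      se <- sqrt(mixture[[code]] * (1 - mixture[[code]]) / n)
      expect_lt(abs(got[[code]] - mixture[[code]]), 4 * se + 1e-9)
    }
  })
})

test_that("annotation confounders defeat classification by set arithmetic", {
  cfg <- sim_config(seed = 31, start_date = "2021-04-15", n_days = 40, nightly_bout_prob = 1,
                    bout_schedule = c("2021-04-25", "2021-05-10"),
                    confounder_fraction = 0.3)
  sim <- simulate_trajectory(cfg)
  cl <- detect_clusters(sim$trajectory)
  ann <- simulate_annotations(cl, sim$truth, cfg)
  classified <- cl$cluster_id[is_fishing_cluster(ann$annotations)]
  expect_setequal(classified, setdiff(ann$true_ids, ann$confounded_ids))
  # confounder fraction 1: nothing classified as fishing
  cfg1 <- sim_config(seed = 31, start_date = "2021-04-15", n_days = 40, nightly_bout_prob = 1,
                     bout_schedule = c("2021-04-25", "2021-05-10"),
                     confounder_fraction = 1)
  ann1 <- simulate_annotations(cl, sim$truth, cfg1)
  expect_equal(sum(is_fishing_cluster(ann1$annotations)), 0)
  expect_setequal(ann1$confounded_ids, ann1$true_ids)
  expect_gt(length(ann1$true_ids), 0)
})
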