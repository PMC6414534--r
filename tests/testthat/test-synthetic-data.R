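geom <- test_geometry()

test_that("a single 10 s fixation script renders 10000 labelled samples", {
  ev <- data.frame(label = "fixation", duration_ms = 10000, x = 960, y = 540,
                   speed_deg_s = NA, heading_deg = NA)
  sim <- simulate_scanpath(scanpath_script(ev), geom, seed = 1)
  expect_length(sim$recording$t, 10000)
  expect_true(all(sim$labels == "fixation"))
  expect_length(sim$labels, length(sim$recording$t))
})

test_that("scripts validate durations and labels", {
  bad <- data.frame(label = "fixation", duration_ms = 9000)
  expect_error(scanpath_script(bad), "durations sum")
  bad <- data.frame(label = c("fixation", "blink"), duration_ms = c(5000, 5000))
  expect_error(scanpath_script(bad), "unknown event label")
  expect_error(scanpath_script(data.frame(label = c("fixation", "fixation"),
                                          duration_ms = c(10001, -1))),
               "positive")
})

test_that("simulated recordings satisfy the recording invariants and are deterministic", {
  for (s in 1:3) {
    set.seed(s)
    scr <- random_scanpath_script(geom, 2500)
    sim1 <- simulate_scanpath(scr, geom, seed = 50 + s)
    sim2 <- simulate_scanpath(scr, geom, seed = 50 + s)
    expect_identical(sim1$recording$x, sim2$recording$x)
    expect_identical(sim1$labels, sim2$labels)
    rec <- sim1$recording
    expect_true(all(diff(rec$t) > 0))
    expect_true(all(rec$x >= 0 & rec$x < geom$width_px))
    expect_true(all(rec$y >= 0 & rec$y < geom$height_px))
    expect_true(all(sim1$labels %in% c("fixation", "saccade", "pursuit")))
  }
})

test_that("scripted saccades are fast enough to trip the velocity threshold", {
  sim <- scripted_fsp(geom)
  tr <- compute_velocity(sim$recording, geom)
  expect_gt(max(tr$speed_raw[sim$labels == "saccade"], na.rm = TRUE), 200)
})

test_that("a pure appearing-point group concentrates its gaze there", {
  spread <- 10
  spec <- cohort_spec(
    geom,
    groups = list(g = list(n_participants = 2, weights = c(1, 0, 0),
                           spread_px = spread, ped_sidewalk_boost = 0,
                           decision_mean = 8, decision_sd = 1)),
    n_trials = 3, trial_duration_ms = 1000, rate_hz = 500,
    jitter_sd_px = 0.5, pedestrian_rate = 0)
  sim <- simulate_cohort(spec, seed = 4, keep_labels = TRUE)
  centre <- c(0.18 * geom$width_px, 0.32 * geom$height_px)
  for (pid in names(sim$recordings)) {
    for (tid in names(sim$recordings[[pid]])) {
      rec <- sim$recordings[[pid]][[tid]]
      lab <- sim$labels[[pid]][[tid]]
      d <- sqrt((rec$x - centre[1])^2 + (rec$y - centre[2])^2)
      expect_lt(max(d[lab != "saccade"]), 4 * spread + 5)
    }
  }
})

test_that("cohort decision counts reproduce the group mean (law of large numbers)", {
  spec <- cohort_spec(
    geom,
    groups = list(g = list(n_participants = 30, weights = c(1, 0, 0),
                           spread_px = 50, ped_sidewalk_boost = 0,
                           decision_mean = 8, decision_sd = 1)),
    n_trials = 6, trial_duration_ms = 200, rate_hz = 250)
  sim <- simulate_cohort(spec, seed = 11)
  per_part <- tapply(sim$decisions$n_presses, sim$decisions$participant_id,
                     mean)
  se <- sd(per_part) / sqrt(length(per_part))
  expect_lt(abs(mean(per_part) - 8), 2 * se + 0.2)
  expect_true(all(sim$decisions$n_presses >= 0))
  expect_true(all(lengths(sim$decisions$press_durations_ms) ==
                    sim$decisions$n_presses))
})

test_that("cohort design and metadata are consistent", {
  spec <- cohort_spec(
    geom,
    groups = list(a = list(n_participants = 2, weights = c(0.5, 0.3, 0.2),
                           spread_px = 80, ped_sidewalk_boost = 0.1,
                           decision_mean = 8, decision_sd = 1),
                  b = list(n_participants = 3, weights = c(0.8, 0.1, 0.1),
                           spread_px = 40, ped_sidewalk_boost = 0,
                           decision_mean = 13, decision_sd = 1)),
    n_trials = 4, trial_duration_ms = 400, rate_hz = 250)
  sim <- simulate_cohort(spec, seed = 2)
  expect_length(sim$recordings, 5)
  expect_equal(nrow(sim$metadata), 4)
  expect_equal(nrow(sim$design), 20)
  expect_setequal(unique(sim$design$age_group), c("a", "b"))
  expect_true(all(sim$metadata$pedestrian_present %in% 0:1))
  expect_equal(sim$metadata$density_class,
               ifelse(sim$metadata$n_vehicles > 3, "high", "low"),
               ignore_attr = TRUE)
})

test_that("traffic renderer is static without vehicles and truthful with them", {
  vid <- render_traffic_video(0, pedestrian_present = 0, n_frames = 12,
                              seed = 1, noise_sd = 0)
  expect_true(all(apply(vid$frames, 3, identical, vid$frames[, , 1])))
  expect_true(all(vid$truth$n_visible == 0))

  vid <- render_traffic_video(4, n_frames = 120, seed = 2)
  expect_equal(max(vid$truth$n_visible), 4)
  expect_true(all(vid$frames >= 0 & vid$frames <= 1))
  expect_true(all(vid$truth$n_visible[seq_len(vid$burnin)] == 0))
})
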