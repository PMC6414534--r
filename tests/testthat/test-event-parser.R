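geom <- test_geometry()

test_that("velocity is zero for a static eye and matches closed-form conversion for motion", {
  tr <- compute_velocity(constant_recording(), geom)
  expect_true(all(tr$speed[!is.na(tr$speed)] == 0))

  # 1 px/ms horizontal: speed = 1000 * deg-per-px at screen centre
  expected <- 1000 * degrees_per_pixel(geom, "horizontal")
  tr <- compute_velocity(ramp_recording(vx = 1), geom)
  expect_equal(expected, 25.91, tolerance = 1e-3)
  expect_equal(max(tr$speed, na.rm = TRUE), expected, tolerance = 1e-6)

  # single-sample 5 px jump: central difference spreads it over 2 ms,
  # giving an unsmoothed two-sample peak of 2.5 px/ms
  rec <- constant_recording(n = 200, x = 500)
  rec$x[100:200] <- 505
  tr <- compute_velocity(rec, geom)
  expect_equal(max(tr$speed_raw, na.rm = TRUE),
               2.5 * 1000 * degrees_per_pixel(geom, "horizontal"),
               tolerance = 1e-6)
})

test_that("velocity is undefined at trace ends, invalid samples and their neighbours", {
  rec <- constant_recording(n = 100)
  rec$valid[50] <- FALSE
  tr <- compute_velocity(rec, geom)
  expect_true(all(is.na(tr$speed[c(1, 49, 50, 51, 100)])))
  expect_false(anyNA(tr$speed[c(2, 48, 52, 99)]))
  expect_error(compute_velocity(constant_recording(n = 2), geom),
               "3 valid samples")
})

test_that("saccade extraction finds exactly the supra-threshold bursts", {
  expect_equal(nrow(extract_saccades(make_trace(rep(20, 500)))), 0)

  sp <- rep(10, 500)
  sp[101:130] <- 300                       # one 30 ms burst
  seg <- extract_saccades(make_trace(sp))
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$idx_start, seg$idx_end), c(101, 130))

  sp[331:360] <- 400                       # second burst, 200 ms later
  seg <- extract_saccades(make_trace(sp))
  expect_equal(nrow(seg), 2)
  # oracle: direct per-sample thresholding
  expect_equal(sort(unlist(Map(seq, seg$idx_start, seg$idx_end))),
               which(sp > 50))
})

test_that("smooth candidates honour the inclusive 100 ms minimum duration", {
  p <- parser_params()
  no_sacc <- extract_saccades(make_trace(rep(100, 10)))[0, ]
  sp <- rep(45, 1000)                      # between bands: never a candidate
  expect_equal(nrow(candidate_smooth_segments(make_trace(sp), no_sacc, p)), 0)

  sp <- rep(45, 1000); sp[101:180] <- 10   # 80 ms: too short
  expect_equal(nrow(candidate_smooth_segments(make_trace(sp), no_sacc, p)), 0)

  sp <- rep(45, 1000); sp[101:250] <- 10   # 150 ms
  cand <- candidate_smooth_segments(make_trace(sp), no_sacc, p)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$idx_start, cand$idx_end), c(101, 250))

  sp <- rep(45, 1000); sp[101:200] <- 30   # exactly 100 ms at the bound
  expect_equal(nrow(candidate_smooth_segments(make_trace(sp), no_sacc, p)), 1)
})

test_that("pursuit score separates moving segments from jittering fixations", {
  p <- parser_params()
  tt <- 0:499

  # noiseless linear ramp: zero residual, score 0
  sc <- pursuit_score(data.frame(t = tt, x = 400 + 0.4 * tt, y = 300), p)
  expect_lt(sc$score, 1e-9)
  expect_equal(sc$rmse, 0, tolerance = 1e-9)

  # stationary with 0.5 px jitter: score of the order of the jitter
  set.seed(7)
  seg <- data.frame(t = tt, x = 960 + rnorm(500, 0, 0.5),
                    y = 540 + rnorm(500, 0, 0.5))
  sc <- pursuit_score(seg, p)
  osc <- oracle_score(seg$t, seg$x, seg$y, p)
  expect_gt(sc$score, 1e-9)
  expect_equal(sc$score, osc$score, tolerance = 1e-2)

  # 10 deg/s ramp over 500 ms: arc length ~193 px, score collapses
  v <- deg_s_to_px_ms(10, geom)
  seg <- data.frame(t = tt, x = 400 + v * tt + rnorm(500, 0, 0.5),
                    y = 300 + rnorm(500, 0, 0.5))
  sc <- pursuit_score(seg, p)
  expect_equal(sc$arc_length, 193, tolerance = 0.03)
  expect_lt(sc$score, 1e-9)
  expect_lt(oracle_score(seg$t, seg$x, seg$y, p)$score, 1e-9)

  expect_error(pursuit_score(data.frame(t = 0:2, x = 1:3, y = 1:3), p),
               "degenerate")
})

test_that("a pure fixation trial parses to a single fixation segment", {
  set.seed(3)
  ev <- data.frame(label = "fixation", duration_ms = 10000, x = 960, y = 540,
                   speed_deg_s = NA, heading_deg = NA)
  sim <- simulate_scanpath(scanpath_script(ev), geom, seed = 3)
  seg <- parse_trial(sim$recording, geom)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$label, "fixation")
  expect_equal(seg$duration_ms, 10000)
})

test_that("a scripted fixation-saccade-pursuit trial is recovered with tight boundaries", {
  sim <- scripted_fsp(geom)
  seg <- parse_trial(sim$recording, geom)
  expect_equal(as.vector(table(factor(seg$label,
                                      c("fixation", "saccade", "pursuit")))),
               c(1, 1, 1))
  truth <- c(0, 4000, 4040, 10000)
  sacc <- seg[seg$label == "saccade", ]
  expect_lt(abs(sacc$t_start_ms - truth[2]), 10)
  expect_lt(abs(sacc$t_end_ms - truth[3]), 10)
  expect_gt(mean(attr(seg, "sample_labels") == sim$labels), 0.95)
})

test_that("segment boundaries equal the one-pass reference implementation on short traces", {
  for (s in 1:6) {
    set.seed(s)
    scr <- random_scanpath_script(geom, duration_ms = 1800)
    sim <- simulate_scanpath(scr, geom, seed = 100 + s)
    rec <- sim$recording
    if (s %% 2 == 0) rec$valid[300:360] <- FALSE      # blink span
    seg <- parse_trial(rec, geom)
    expect_identical(attr(seg, "sample_labels"), oracle_labels(rec, geom),
                     label = sprintf("seed %d", s))
  }
})

test_that("segments partition the trial and summaries add up", {
  for (s in 1:5) {
    set.seed(s)
    sim <- simulate_scanpath(random_scanpath_script(geom, 3000), geom,
                             seed = 200 + s)
    rec <- sim$recording
    if (s == 2) rec$valid[1000:1200] <- FALSE
    seg <- parse_trial(rec, geom)
    expect_identical(sum(seg$duration_ms), attr(seg, "trial_duration_ms"))
    expect_true(all(seg$t_start_ms[-1] == seg$t_end_ms[-nrow(seg)]))
    summ <- summarize_events(seg)
    expect_equal(sum(summ$total_ms), attr(seg, "trial_duration_ms"))
    expect_equal(sum(summ$proportion), 1)
    expect_equal(sum(summ$count), nrow(seg))
  }
})

test_that("summaries of degenerate inputs are all zeros or a single block", {
  ev <- data.frame(label = "fixation", duration_ms = 10000, x = 960, y = 540,
                   speed_deg_s = NA, heading_deg = NA)
  sim <- simulate_scanpath(scanpath_script(ev), geom, seed = 1)
  seg <- parse_trial(sim$recording, geom)
  summ <- summarize_events(seg, 10000)
  expect_equal(summ$count[summ$label == "fixation"], 1L)
  expect_equal(summ$total_ms[summ$label == "fixation"], 10000)
  expect_equal(summ$proportion[summ$label == "fixation"], 1)

  empty <- summarize_events(seg[0, ], 10000)
  expect_true(all(empty$count == 0) && all(empty$total_ms == 0))
})

test_that("raising the saccade threshold never increases the saccade count", {
  set.seed(9)
  sim <- simulate_scanpath(random_scanpath_script(geom, 5000), geom, seed = 9)
  tr <- compute_velocity(sim$recording, geom)
  counts <- vapply(c(40, 50, 70, 120, 300), function(th) {
    nrow(extract_saccades(tr, parser_params(saccade_vel_thresh = th)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical input yields identical segments (determinism)", {
  sim <- scripted_fsp(geom, seed = 5)
  s1 <- parse_trial(sim$recording, geom)
  s2 <- parse_trial(sim$recording, geom)
  expect_identical(s1, s2)
})

test_that("QC removes majority-noise trials and excludes majority-removed participants", {
  p <- parser_params(vel_window_ms = 1)     # no smoothing: exact fractions
  n <- 50
  fast <- function(frac, trial) {
    # ramp at 40 px/ms (~1000 deg/s) over the first `frac` of the trial,
    # then hold: supra-threshold on (round(frac * n) - 1) of the n samples
    k <- round(frac * n)
    x <- c(500 + 40 * seq_len(k), rep(500 + 40 * k, n - k))
    gaze_recording("p", trial, t = 0:(n - 1), x = x, y = rep(500, n))
  }
  slow <- function(trial) constant_recording(n)

  trials <- list(
    keep1 = list(fast(0.6, "a"), slow("b"), slow("c")),       # 1 of 3 removed
    drop1 = list(fast(0.8, "a"), fast(0.7, "b"), slow("c")))  # 2 of 3 removed
  names(trials$keep1) <- names(trials$drop1) <- c("a", "b", "c")
  res <- qc_filter(trials, geom, p)
  expect_equal(res$excluded_participants, "drop1")
  expect_equal(names(res$kept), "keep1")
  expect_equal(length(res$kept$keep1), 2)
  expect_equal(nrow(res$removed_trials), 3)

  # boundary: exactly half removed -> retained (strict majority rule)
  half <- list(p1 = list(fast(0.9, "a"), slow("b")))
  names(half$p1) <- c("a", "b")
  res <- qc_filter(half, geom, p)
  expect_length(res$excluded_participants, 0)
  expect_equal(length(res$kept$p1), 1)
})
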