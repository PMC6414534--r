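# shared fixtures: the study monitor and small scripted recordings

test_geometry <- function() screen_geometry(1920, 1080, 521, 293, 600)

# recording with a constant position
constant_recording <- function(n = 1000, x = 960, y = 540, rate_hz = 1000) {
  gaze_recording("p1", "t1", t = (seq_len(n) - 1) * 1000 / rate_hz,
                 x = rep(x, n), y = rep(y, n), rate_hz = rate_hz)
}

# recording moving at a constant pixel velocity (px per ms)
ramp_recording <- function(n = 1000, vx = 1, vy = 0, x0 = 100, y0 = 540) {
  tt <- seq_len(n) - 1
  gaze_recording("p1", "t1", t = tt, x = x0 + vx * tt, y = y0 + vy * tt)
}

# hand-built velocity trace for direct run-detection tests
make_trace <- function(speed, dt = 1, valid = rep(TRUE, length(speed))) {
  structure(data.frame(t = (seq_along(speed) - 1) * dt, speed = speed,
                       speed_raw = speed),
            class = c("velocity_trace", "data.frame"),
            dt_ms = dt, valid = valid)
}

# a three-event scripted trial: fixation -> saccade -> pursuit
scripted_fsp <- function(geom, seed = 42) {
  ev <- data.frame(label = c("fixation", "saccade", "pursuit"),
                   duration_ms = c(4000, 40, 5960),
                   x = c(400, NA, 900), y = c(300, NA, 600),
                   speed_deg_s = c(NA, NA, 10),
                   heading_deg = c(NA, NA, 20))
  simulate_scanpath(scanpath_script(ev), geom, seed = seed)
}
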