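#' Scanpath script: the ground-truth plan of a simulated trial
#'
#' An ordered list of oculomotor events (fixations, saccades, pursuits)
#' with durations and spatial targets, from which a 1000 Hz gaze recording
#' can be rendered sample by sample. Durations must be positive and sum to
#' the trial duration.
#'
#' @param events Data.frame with columns `label` (`fixation`, `saccade`,
#'   `pursuit`), `duration_ms`, `x`, `y` (target / start position in px;
#'   `NA` to continue from the current position), `speed_deg_s` and
#'   `heading_deg` (pursuit only; heading 0 = rightward, 90 = downward).
#' @param jitter_sd_px SD of isotropic Gaussian sample jitter in pixels.
#' @param trial_duration_ms Expected total duration (default 10000 ms).
#' @return A list of class `scanpath_script`.
#' @export
scanpath_script <- function(events, jitter_sd_px = 0.5,
                            trial_duration_ms = 10000) {
  stopifnot(all(c("label", "duration_ms") %in% names(events)))
  if (!all(events$label %in% c("fixation", "saccade", "pursuit"))) {
    stop("scanpath_script: unknown event label")
  }
  if (any(events$duration_ms <= 0)) {
    stop("scanpath_script: event durations must be positive")
  }
  if (abs(sum(events$duration_ms) - trial_duration_ms) > 1e-9) {
    stop(sprintf("scanpath_script: durations sum to %g ms, expected %g ms",
                 sum(events$duration_ms), trial_duration_ms))
  }
  for (col in c("x", "y", "speed_deg_s", "heading_deg")) {
    if (is.null(events[[col]])) events[[col]] <- NA_real_
  }
  structure(list(events = events, jitter_sd_px = jitter_sd_px,
                 trial_duration_ms = trial_duration_ms),
            class = "scanpath_script")
}

#' Render a scanpath script into a gaze recording with ground truth
#'
#' Fixations are a static position plus Gaussian jitter; pursuits move
#' linearly at the scripted speed and heading; saccades are ballistic
#' raised-cosine transitions from the current position to the next event's
#' start position, so short scripted saccades over typical amplitudes reach
#' peak velocities well above 200 deg/s. Every sample carries its
#' generating event label.
#'
#' @param script A [scanpath_script()].
#' @param geometry A [screen_geometry()].
#' @param rate_hz Sampling rate (default 1000).
#' @param participant_id,trial_id Identifiers for the recording.
#' @param seed Optional integer seed (local RNG, does not disturb the
#'   global stream when supplied).
#' @return A list with `recording` (a [gaze_recording()]) and `labels`
#'   (character vector, one ground-truth label per sample).
#' @export
simulate_scanpath <- function(script, geometry, rate_hz = 1000,
                              participant_id = "sim", trial_id = "t1",
                              seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ev <- script$events
  dt <- 1000 / rate_hz
  n_ev <- round(ev$duration_ms / dt)
  total_n <- sum(n_ev)
  x <- y <- numeric(total_n)
  labels <- character(total_n)
  cx <- geometry$width_px / 2
  cy <- geometry$height_px / 2
  pos <- c(cx, cy)

  # start position of event k (for saccade look-ahead)
  start_of <- function(k, current) {
    if (k > nrow(ev)) return(current)
    if (ev$label[k] == "saccade") return(start_of(k + 1, current))
    if (is.na(ev$x[k])) current else c(ev$x[k], ev$y[k])
  }

  off <- 0L
  for (k in seq_len(nrow(ev))) {
    nk <- n_ev[k]
    if (nk == 0) next
    idx <- off + seq_len(nk)
    lab <- ev$label[k]
    if (lab == "fixation") {
      tgt <- if (is.na(ev$x[k])) pos else c(ev$x[k], ev$y[k])
      px <- rep(tgt[1], nk)
      py <- rep(tgt[2], nk)
      pos <- tgt
    } else if (lab == "pursuit") {
      p0 <- if (is.na(ev$x[k])) pos else c(ev$x[k], ev$y[k])
      v <- deg_s_to_px_ms(ev$speed_deg_s[k], geometry)       # px/ms
      th <- ev$heading_deg[k] * pi / 180
      tt <- (seq_len(nk) - 1) * dt
      px <- p0[1] + v * cos(th) * tt
      py <- p0[2] + v * sin(th) * tt
      pos <- c(px[nk] + v * cos(th) * dt, py[nk] + v * sin(th) * dt)
    } else {                                                  # saccade
      tgt <- start_of(k + 1, pos)
      tau <- seq_len(nk) / nk
      s <- (1 - cos(pi * tau)) / 2                            # raised cosine
      px <- pos[1] + (tgt[1] - pos[1]) * s
      py <- pos[2] + (tgt[2] - pos[2]) * s
      pos <- tgt
    }
    x[idx] <- px
    y[idx] <- py
    labels[idx] <- lab
    off <- off + nk
  }

  if (script$jitter_sd_px > 0) {
    x <- x + stats::rnorm(total_n, 0, script$jitter_sd_px)
    y <- y + stats::rnorm(total_n, 0, script$jitter_sd_px)
  }
  x <- pmin(pmax(x, 0), geometry$width_px - 1)
  y <- pmin(pmax(y, 0), geometry$height_px - 1)

  rec <- gaze_recording(participant_id, trial_id,
                        t = (seq_len(total_n) - 1) * dt,
                        x = x, y = y, rate_hz = rate_hz)
  list(recording = rec, labels = labels)
}

# draw a target position from a group's spatial bias mixture
draw_bias_target <- function(bias, geometry) {
  comp <- sample(c("appear", "sidewalk", "vehicle"), 1, prob = bias$weights)
  if (comp == "appear") {
    c(stats::rnorm(1, bias$appear_centre[1], bias$spread_px),
      stats::rnorm(1, bias$appear_centre[2], bias$spread_px), 0)
  } else if (comp == "sidewalk") {
    c(stats::runif(1, 0.15 * geometry$width_px, 0.85 * geometry$width_px),
      stats::rnorm(1, bias$sidewalk_y, 0.5 * bias$spread_px), 0)
  } else {
    c(stats::rnorm(1, bias$appear_centre[1], bias$spread_px),
      stats::rnorm(1, bias$appear_centre[2], bias$spread_px), 1)
  }
}

#' Random scanpath script for one trial
#'
#' Alternates fixations (and occasional pursuits) with short saccades until
#' the trial duration is filled, the final fixation absorbing the
#' remainder. Targets are either uniform over the screen (`bias = NULL`,
#' the spatially diffuse null case) or drawn from a group's bias mixture
#' over the vehicle appearing point, the sidewalk band, and
#' vehicle-following pursuit along the road.
#'
#' @param geometry A [screen_geometry()].
#' @param duration_ms Trial duration (default 10000).
#' @param jitter_sd_px Sample jitter SD (default 0.5 px).
#' @param bias Optional bias mixture (see [cohort_spec()]).
#' @param p_pursuit Probability that a gaze epoch is a pursuit rather than
#'   a fixation when no bias mixture is given.
#' @return A [scanpath_script()].
#' @export
random_scanpath_script <- function(geometry, duration_ms = 10000,
                                   jitter_sd_px = 0.5, bias = NULL,
                                   p_pursuit = 0.25) {
  margin <- 120
  w <- geometry$width_px
  h <- geometry$height_px
  rows <- list()
  budget <- duration_ms
  min_fix <- 200
  first <- TRUE
  while (budget > 0) {
    if (!first) {
      sac_dur <- round(stats::runif(1, 30, 60))
      if (budget - sac_dur < min_fix) break
      rows[[length(rows) + 1]] <- data.frame(
        label = "saccade", duration_ms = sac_dur, x = NA_real_,
        y = NA_real_, speed_deg_s = NA_real_, heading_deg = NA_real_)
      budget <- budget - sac_dur
    }
    if (is.null(bias)) {
      tgt <- c(stats::runif(1, margin, w - margin),
               stats::runif(1, margin, h - margin))
      is_pursuit <- stats::runif(1) < p_pursuit
      heading <- atan2(h / 2 - tgt[2], w / 2 - tgt[1]) * 180 / pi
    } else {
      d <- draw_bias_target(bias, geometry)
      tgt <- pmin(pmax(d[1:2], margin), c(w, h) - margin)
      is_pursuit <- d[3] == 1
      heading <- bias$road_heading_deg
    }
    if (is_pursuit) {
      dur <- round(stats::runif(1, 300, 900))
      dur <- min(dur, budget)
      if (dur < 300) is_pursuit <- FALSE
    }
    if (is_pursuit) {
      rows[[length(rows) + 1]] <- data.frame(
        label = "pursuit", duration_ms = dur, x = tgt[1], y = tgt[2],
        speed_deg_s = stats::runif(1, 8, 15), heading_deg = heading)
    } else {
      dur <- round(stats::runif(1, min_fix, 800))
      dur <- min(dur, budget)
      rows[[length(rows) + 1]] <- data.frame(
        label = "fixation", duration_ms = dur, x = tgt[1], y = tgt[2],
        speed_deg_s = NA_real_, heading_deg = NA_real_)
    }
    budget <- budget - dur
    first <- FALSE
  }
  ev <- do.call(rbind, rows)
  # absorb any remainder into the last gaze epoch
  if (budget > 0) {
    ev$duration_ms[nrow(ev)] <- ev$duration_ms[nrow(ev)] + budget
  }
  scanpath_script(ev, jitter_sd_px = jitter_sd_px,
                  trial_duration_ms = duration_ms)
}

default_bias <- function(weights, spread_px, geometry) {
  list(weights = weights, spread_px = spread_px,
       appear_centre = c(0.18 * geometry$width_px,
                         0.32 * geometry$height_px),
       sidewalk_y = 0.85 * geometry$height_px,
       road_heading_deg = 20)
}

#' Specification of a simulated cohort
#'
#' Defines the groups (sizes, spatial gaze-bias mixtures over appearing
#' point / sidewalk / vehicle-following, decision-count distributions) and
#' the trial design. Defaults follow the experimental design being
#' emulated: 100 trials of 10 s at 1000 Hz; child groups' crossing-decision
#' distributions use the reference cluster parameters (means 8 and 13,
#' SD 1), adults matching the older children.
#'
#' @param geometry A [screen_geometry()].
#' @param groups Named list; each element a list with `n_participants`,
#'   `weights` (appear / sidewalk / vehicle-following mixture, sums to 1),
#'   `spread_px`, `ped_sidewalk_boost` (added to the sidewalk weight on
#'   pedestrian trials before renormalisation), `decision_mean`,
#'   `decision_sd`.
#' @param n_trials,trial_duration_ms,rate_hz Trial design.
#' @param jitter_sd_px Sample jitter SD.
#' @param pedestrian_rate Fraction of trials with a pedestrian distractor.
#' @param vehicle_lambda Two Poisson means for the low/high traffic mix
#'   (50/50), emulating the bimodal traffic-density distribution.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(geometry,
                        groups = list(
                          child_5_10 = list(
                            n_participants = 29,
                            weights = c(0.45, 0.30, 0.25), spread_px = 160,
                            ped_sidewalk_boost = 0.25,
                            decision_mean = 8, decision_sd = 1),
                          child_11_15 = list(
                            n_participants = 28,
                            weights = c(0.70, 0.10, 0.20), spread_px = 90,
                            ped_sidewalk_boost = 0.05,
                            decision_mean = 13, decision_sd = 1),
                          adult = list(
                            n_participants = 10,
                            weights = c(0.80, 0.05, 0.15), spread_px = 60,
                            ped_sidewalk_boost = 0.02,
                            decision_mean = 13, decision_sd = 1)),
                        n_trials = 100, trial_duration_ms = 10000,
                        rate_hz = 1000, jitter_sd_px = 0.5,
                        pedestrian_rate = 0.5,
                        vehicle_lambda = c(1.5, 5.5)) {
  for (g in groups) {
    stopifnot(abs(sum(g$weights) - 1) < 1e-9, g$n_participants >= 1)
  }
  stopifnot(n_trials >= 1)
  structure(list(geometry = geometry, groups = groups, n_trials = n_trials,
                 trial_duration_ms = trial_duration_ms, rate_hz = rate_hz,
                 jitter_sd_px = jitter_sd_px,
                 pedestrian_rate = pedestrian_rate,
                 vehicle_lambda = vehicle_lambda),
            class = "cohort_spec")
}

#' Simulate a full cohort: recordings, metadata, decisions, design
#'
#' Every participant watches the same trial set. Scanpaths are drawn from
#' the participant's group bias mixture (pedestrian trials upweight the
#' sidewalk component by the group's boost); per-participant mean decision
#' counts are drawn from the group's normal distribution, per-trial counts
#' around that mean are rounded and floored at zero, and press durations
#' are log-normal.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @param keep_labels Keep per-sample ground-truth labels (memory heavy for
#'   large cohorts).
#' @return A list with `recordings` (nested list participant -> trial),
#'   `labels` (same shape, if kept), `metadata` (per-trial data.frame),
#'   `decisions` (per participant x trial), and `design` (per participant
#'   x trial with `age_group`, `pedestrian_present`, `density_class`).
#' @export
simulate_cohort <- function(spec, seed = 1, keep_labels = FALSE) {
  set.seed(seed)
  geom <- spec$geometry
  n_trials <- spec$n_trials

  trial_ids <- sprintf("trial%03d", seq_len(n_trials))
  ped <- as.integer(stats::runif(n_trials) < spec$pedestrian_rate)
  lam <- sample(spec$vehicle_lambda, n_trials, replace = TRUE)
  n_veh <- stats::rpois(n_trials, lam)
  metadata <- data.frame(trial_id = trial_ids, pedestrian_present = ped,
                         n_vehicles = n_veh,
                         density_class = density_split(n_veh),
                         stringsAsFactors = FALSE)

  recordings <- list()
  labels <- list()
  decisions <- list()
  design <- list()
  pnum <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    bias0 <- default_bias(g$weights, g$spread_px, geom)
    for (i in seq_len(g$n_participants)) {
      pnum <- pnum + 1L
      pid <- sprintf("p%03d", pnum)
      m_p <- stats::rnorm(1, g$decision_mean, g$decision_sd)
      recs <- vector("list", n_trials)
      labs <- vector("list", n_trials)
      dec_rows <- vector("list", n_trials)
      for (j in seq_len(n_trials)) {
        bias <- bias0
        if (ped[j] == 1) {
          w <- bias$weights
          w[2] <- w[2] + g$ped_sidewalk_boost
          bias$weights <- w / sum(w)
        }
        scr <- random_scanpath_script(geom, spec$trial_duration_ms,
                                      spec$jitter_sd_px, bias = bias)
        sim <- simulate_scanpath(scr, geom, spec$rate_hz,
                                 participant_id = pid,
                                 trial_id = trial_ids[j])
        recs[[j]] <- sim$recording
        if (keep_labels) labs[[j]] <- sim$labels
        n_press <- max(0, round(stats::rnorm(1, m_p, 2)))
        dec_rows[[j]] <- data.frame(
          participant_id = pid, trial_id = trial_ids[j],
          n_presses = n_press, stringsAsFactors = FALSE)
        dec_rows[[j]]$press_durations_ms <-
          list(stats::rlnorm(n_press, log(500), 0.4))
      }
      names(recs) <- trial_ids
      recordings[[pid]] <- recs
      if (keep_labels) {
        names(labs) <- trial_ids
        labels[[pid]] <- labs
      }
      decisions[[pid]] <- do.call(rbind, dec_rows)
      design[[pid]] <- data.frame(
        participant_id = pid, stimulus_id = trial_ids,
        age_group = gname, pedestrian_present = ped,
        density_class = metadata$density_class, stringsAsFactors = FALSE)
    }
  }
  out <- list(recordings = recordings, metadata = metadata,
              decisions = do.call(rbind, c(decisions,
                                           make.row.names = FALSE)),
              design = do.call(rbind, c(design, make.row.names = FALSE)))
  if (keep_labels) out$labels <- labels
  out
}

#' Render a toy traffic video with ground truth
#'
#' A static textured background; vehicles as bright rectangles entering at
#' a fixed appearing point on the left end of the road line and moving
#' right, staggered so that all co-occur on screen; optionally a small slow
#' pedestrian blob on the sidewalk band. An initial vehicle-free burn-in
#' lets a background model stabilise.
#'
#' @param n_vehicles Number of vehicles (>= 0).
#' @param pedestrian_present 0/1.
#' @param n_frames Total frames (default 120, of which `burnin` are
#'   vehicle-free).
#' @param seed Integer seed.
#' @param width,height Frame size in px.
#' @param burnin Vehicle-free leading frames.
#' @param noise_sd Per-frame Gaussian sensor noise SD (intensity units).
#' @return A list with `frames` (array `height x width x n_frames`, values
#'   in \[0, 1\]), `frame_rate`, `burnin`, `truth` (data.frame `frame`,
#'   `n_visible`) and `n_vehicles`.
#' @export
render_traffic_video <- function(n_vehicles, pedestrian_present = 0,
                                 n_frames = 120, seed = 1,
                                 width = 160, height = 120, burnin = 30,
                                 noise_sd = 0.01) {
  stopifnot(n_vehicles >= 0, n_frames >= 2)
  set.seed(seed)
  veh_w <- 14
  veh_h <- 8
  spacing <- 24
  speed <- 3                                 # px/frame
  road_y <- round(height * 0.45)
  bg <- matrix(rep(seq(0.25, 0.45, length.out = height), width),
               height, width)
  bg <- bg + matrix(stats::runif(height * width, -0.03, 0.03),
                    height, width)

  frames <- array(0, dim = c(height, width, n_frames))
  n_visible <- integer(n_frames)
  x0 <- -(seq_len(max(n_vehicles, 0)) - 1) * spacing - veh_w
  ped_x <- stats::runif(1, 0.2, 0.6) * width
  ped_y <- round(height * 0.82)

  for (f in seq_len(n_frames)) {
    img <- bg
    if (f > burnin) {
      adv <- (f - burnin) * speed
      for (k in seq_len(n_vehicles)) {
        xl <- x0[k] + adv
        xr <- xl + veh_w - 1
        if (xr < 0 || xl > width - 1) next
        cols <- max(0, xl):min(width - 1, xr) + 1
        rows <- (road_y - veh_h %/% 2):(road_y + veh_h %/% 2)
        img[rows, cols] <- 0.92
        n_visible[f] <- n_visible[f] + 1L
      }
      if (pedestrian_present == 1) {
        px <- round(ped_x + (f - burnin) * 0.5)
        if (px >= 1 && px + 3 <= width) {
          img[ped_y:(ped_y + 5), px:(px + 3)] <- 0.1
        }
      }
    }
    img <- img + matrix(stats::rnorm(height * width, 0, noise_sd),
                        height, width)
    frames[, , f] <- pmin(pmax(img, 0), 1)
  }
  list(frames = frames, frame_rate = 25, burnin = burnin,
       truth = data.frame(frame = seq_len(n_frames),
                          n_visible = n_visible),
       n_vehicles = n_vehicles)
}
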