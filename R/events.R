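#' Parameters of the oculomotor event parser
#'
#' Thresholds for parsing a gaze sample stream into fixations, saccades and
#' smooth pursuits. Saccades are samples whose angular speed exceeds
#' `saccade_vel_thresh`; smooth-pursuit candidates are runs that stay at or
#' below `pursuit_vel_max` for at least `pursuit_min_dur_ms`; a candidate is
#' labelled pursuit when its dispersion score (polynomial-fit RMSE divided
#' by the exponential of the fitted curve's arc length) falls below
#' `score_thresh` and its displacement is at least
#' `min_pursuit_displacement_px`.
#'
#' @param saccade_vel_thresh Saccade velocity threshold, deg/s.
#' @param pursuit_vel_max Maximum speed of a smooth segment, deg/s.
#' @param pursuit_min_dur_ms Minimum smooth-segment duration, ms.
#' @param score_thresh Pursuit score threshold (dimensionless).
#' @param poly_degree Degree of the polynomial fitted to x(t) and y(t).
#' @param vel_window_ms Width of the centred moving-average velocity
#'   smoother, ms.
#' @param min_pursuit_displacement_px Minimum displacement for a pursuit
#'   label, pixels; guards degenerate zero-noise fixations whose fit is
#'   exact.
#' @param min_segment_ms Transition slivers shorter than this (ms) are
#'   absorbed into the longer neighbouring segment; suppresses spurious
#'   few-sample fixations at event boundaries created by velocity
#'   smoothing.
#'
#' @return A list of class `parser_params`.
#' @export
parser_params <- function(saccade_vel_thresh = 50,
                          pursuit_vel_max = 30,
                          pursuit_min_dur_ms = 100,
                          score_thresh = 1e-9,
                          poly_degree = 2,
                          vel_window_ms = 20,
                          min_pursuit_displacement_px = 10,
                          min_segment_ms = 20) {
  p <- list(saccade_vel_thresh = saccade_vel_thresh,
            pursuit_vel_max = pursuit_vel_max,
            pursuit_min_dur_ms = pursuit_min_dur_ms,
            score_thresh = score_thresh,
            poly_degree = poly_degree,
            vel_window_ms = vel_window_ms,
            min_pursuit_displacement_px = min_pursuit_displacement_px,
            min_segment_ms = min_segment_ms)
  if (any(unlist(p) <= 0)) stop("parser_params: all parameters must be positive")
  if (p$pursuit_vel_max >= p$saccade_vel_thresh) {
    stop("parser_params: pursuit_vel_max must be below saccade_vel_thresh")
  }
  structure(p, class = "parser_params")
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end), inclusive
runs_of <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# NA-aware centred moving average via cumulative sums
moving_average_na <- function(x, half) {
  n <- length(x)
  if (half < 1) return(x)
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(as.numeric(ok))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  s <- cs[hi] - c(0, cs)[lo]
  m <- cn[hi] - c(0, cn)[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  out[!ok] <- NA_real_
  out
}

#' Per-sample angular velocity of a gaze recording
#'
#' Central-difference displacement per axis, converted to degrees of visual
#' angle per second with the local linear factor at screen centre, then
#' smoothed with a centred moving average of width `vel_window_ms`. Speed
#' is undefined (`NA`) for invalid samples, for samples adjacent to an
#' invalid span and at the first and last sample of the trace.
#'
#' @param recording A [gaze_recording()].
#' @param geometry A [screen_geometry()].
#' @param params A [parser_params()].
#'
#' @return A data.frame of class `velocity_trace` with columns `t`,
#'   `speed` (smoothed, deg/s) and `speed_raw` (unsmoothed, deg/s);
#'   attributes carry the sample period and validity.
#' @export
compute_velocity <- function(recording, geometry, params = parser_params()) {
  if (sum(recording$valid) < 3) {
    stop("compute_velocity: need at least 3 valid samples")
  }
  t <- recording$t
  n <- length(t)
  x <- recording$x
  y <- recording$y
  x[!recording$valid] <- NA_real_
  y[!recording$valid] <- NA_real_
  dpp_h <- degrees_per_pixel(geometry, "horizontal")
  dpp_v <- degrees_per_pixel(geometry, "vertical")

  vx <- vy <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    dt2 <- t[i + 1] - t[i - 1]                       # ms
    vx[i] <- (x[i + 1] - x[i - 1]) / dt2 * dpp_h     # deg/ms
    vy[i] <- (y[i + 1] - y[i - 1]) / dt2 * dpp_v
  }
  speed_raw <- sqrt(vx^2 + vy^2) * 1000              # deg/s
  speed_raw[!recording$valid] <- NA_real_

  dt <- 1000 / recording$rate_hz
  w <- max(1L, as.integer(round(params$vel_window_ms / dt)))
  half <- w %/% 2L
  speed <- moving_average_na(speed_raw, half)

  structure(
    data.frame(t = t, speed = speed, speed_raw = speed_raw),
    class = c("velocity_trace", "data.frame"),
    dt_ms = dt, valid = recording$valid)
}

segments_from_runs <- function(runs, t, dt, label) {
  if (!nrow(runs)) {
    return(data.frame(label = character(0), idx_start = integer(0),
                      idx_end = integer(0), t_start_ms = numeric(0),
                      t_end_ms = numeric(0)))
  }
  data.frame(label = label, idx_start = runs$start, idx_end = runs$end,
             t_start_ms = t[runs$start], t_end_ms = t[runs$end] + dt)
}

#' Extract saccade segments from a velocity trace
#'
#' Maximal runs of samples whose smoothed speed exceeds the saccade
#' velocity threshold.
#'
#' @param trace A `velocity_trace` from [compute_velocity()].
#' @param params A [parser_params()].
#' @return A data.frame of saccade segments (possibly empty) with sample
#'   indices and half-open time intervals.
#' @export
extract_saccades <- function(trace, params = parser_params()) {
  runs <- runs_of(trace$speed > params$saccade_vel_thresh)
  segments_from_runs(runs, trace$t, attr(trace, "dt_ms"), "saccade")
}

#' Candidate smooth-pursuit segments
#'
#' Maximal runs, outside saccades, whose speed stays at or below
#' `pursuit_vel_max` for at least `pursuit_min_dur_ms` (inclusive bound).
#' Shorter sub-threshold runs, and samples in the intermediate velocity
#' band between the pursuit and saccade thresholds, default to fixation.
#'
#' @inheritParams extract_saccades
#' @param saccades Saccade segments from [extract_saccades()].
#' @return A data.frame of candidate intervals.
#' @export
candidate_smooth_segments <- function(trace, saccades,
                                      params = parser_params()) {
  dt <- attr(trace, "dt_ms")
  in_saccade <- rep(FALSE, nrow(trace))
  if (nrow(saccades)) {
    for (k in seq_len(nrow(saccades))) {
      in_saccade[saccades$idx_start[k]:saccades$idx_end[k]] <- TRUE
    }
  }
  mask <- !is.na(trace$speed) & trace$speed <= params$pursuit_vel_max &
    !in_saccade
  runs <- runs_of(mask)
  if (nrow(runs)) {
    dur <- (runs$end - runs$start + 1) * dt
    runs <- runs[dur >= params$pursuit_min_dur_ms, , drop = FALSE]
  }
  segments_from_runs(runs, trace$t, dt, "smooth")
}

poly_design <- function(tc, degree) {
  outer(tc, 0:degree, `^`)
}

#' Smooth-pursuit dispersion score of a gaze segment
#'
#' Fits a polynomial of degree `poly_degree` to x(t) and y(t) (after one
#' pass of robust outlier removal: samples whose pooled residual magnitude
#' deviates from the median by more than 3 MAD-based SDs are dropped),
#' computes the pooled root-mean-square residual `P_RMSE` in pixels and the
#' numerically integrated arc length `A` of the fitted 2D curve in pixels,
#' and returns `P_RMSE / exp(A)`. Scores below the parser threshold mark
#' smooth pursuit: a genuinely moving eye traces a long fitted curve, so
#' `exp(A)` is enormous and the score collapses; a jittering fixation
#' yields a near-point curve and a score of the order of the jitter itself.
#'
#' @param segment_samples Data.frame with columns `t`, `x`, `y` (valid
#'   samples only).
#' @param params A [parser_params()].
#' @return A list with `score`, `rmse`, `arc_length`, `displacement`
#'   (straight-line distance between fitted endpoints, px) and `n_used`.
#' @export
pursuit_score <- function(segment_samples, params = parser_params()) {
  deg <- params$poly_degree
  t <- segment_samples$t
  x <- segment_samples$x
  y <- segment_samples$y
  if (length(t) < deg + 2) {
    stop("pursuit_score: degenerate segment (need >= poly_degree + 2 samples)")
  }
  tc <- (t - mean(t)) / 1000                      # seconds, centred
  fit_resid <- function(keep) {
    X <- poly_design(tc[keep], deg)
    bx <- qr.solve(X, x[keep])
    by <- qr.solve(X, y[keep])
    list(bx = bx, by = by,
         rx = x[keep] - X %*% bx, ry = y[keep] - X %*% by)
  }
  f <- fit_resid(rep(TRUE, length(tc)))
  r <- sqrt(f$rx^2 + f$ry^2)
  s <- stats::mad(r)
  keep <- if (s > 0) abs(r - stats::median(r)) <= 3 * s else
    rep(TRUE, length(r))
  if (sum(keep) >= deg + 2 && !all(keep)) f <- fit_resid(keep)
  else keep <- rep(TRUE, length(tc))

  rmse <- sqrt(mean(c(f$rx, f$ry)^2))

  # arc length of the fitted curve over the kept time span (trapezoid rule
  # on the analytic derivative)
  tk <- tc[keep]
  grid <- seq(min(tk), max(tk), length.out = max(200L, 2L * sum(keep)))
  dcoef <- function(b) b[-1] * seq_len(deg)
  dx <- poly_design(grid, deg - 1) %*% dcoef(f$bx)
  dy <- poly_design(grid, deg - 1) %*% dcoef(f$by)
  sp <- sqrt(dx^2 + dy^2)
  h <- diff(grid)
  arc <- sum((sp[-1] + sp[-length(sp)]) / 2 * h)

  ends <- poly_design(range(tk), deg)
  p0 <- c(ends[1, ] %*% f$bx, ends[1, ] %*% f$by)
  p1 <- c(ends[2, ] %*% f$bx, ends[2, ] %*% f$by)

  list(score = rmse * exp(-arc), rmse = rmse, arc_length = arc,
       displacement = sqrt(sum((p1 - p0)^2)), n_used = sum(keep))
}

# relabel non-missing runs shorter than min_ms to the longer non-missing
# neighbouring run; repeats until stable
absorb_slivers <- function(lab, dt, min_ms, max_pass = 50) {
  for (pass in seq_len(max_pass)) {
    r <- rle(lab)
    k <- length(r$lengths)
    if (k < 2) break
    short <- which(r$values != "missing" & r$lengths * dt < min_ms)
    changed <- FALSE
    for (i in short) {
      left <- if (i > 1 && r$values[i - 1] != "missing") i - 1 else NA
      right <- if (i < k && r$values[i + 1] != "missing") i + 1 else NA
      pick <- if (is.na(left)) right
      else if (is.na(right)) left
      else if (r$lengths[left] >= r$lengths[right]) left else right
      if (!is.na(pick) && r$values[pick] != r$values[i]) {
        r$values[i] <- r$values[pick]
        changed <- TRUE
      }
    }
    if (!changed) break
    lab <- inverse.rle(r)
  }
  lab
}

#' Parse one trial into labelled oculomotor events
#'
#' Full event parse: velocity computation, saccade extraction by velocity
#' threshold, smooth-candidate isolation, pursuit scoring, and fixation by
#' exclusion. Every sample receives exactly one label (`fixation`,
#' `saccade`, `pursuit` or `missing`); contiguous equal labels are merged
#' into segments with half-open intervals `[t_start, t_end)` so that the
#' segments partition the trial duration exactly.
#'
#' @inheritParams compute_velocity
#' @return A data.frame of event segments with columns `trial_id`, `label`,
#'   `t_start_ms`, `t_end_ms`, `duration_ms`, `mean_x`, `mean_y`, `score`;
#'   attribute `sample_labels` holds the per-sample labels and attribute
#'   `trial_duration_ms` the trial duration.
#' @export
parse_trial <- function(recording, geometry, params = parser_params()) {
  trace <- compute_velocity(recording, geometry, params)
  n <- nrow(trace)
  dt <- attr(trace, "dt_ms")

  lab <- rep("fixation", n)
  lab[!recording$valid] <- "missing"

  saccades <- extract_saccades(trace, params)
  if (nrow(saccades)) {
    for (k in seq_len(nrow(saccades))) {
      idx <- saccades$idx_start[k]:saccades$idx_end[k]
      lab[idx][recording$valid[idx]] <- "saccade"
    }
  }

  cands <- candidate_smooth_segments(trace, saccades, params)
  if (nrow(cands)) {
    for (k in seq_len(nrow(cands))) {
      idx <- cands$idx_start[k]:cands$idx_end[k]
      vidx <- idx[recording$valid[idx]]
      if (length(vidx) < params$poly_degree + 2) next
      sc <- pursuit_score(data.frame(t = recording$t[vidx],
                                     x = recording$x[vidx],
                                     y = recording$y[vidx]), params)
      if (sc$score < params$score_thresh &&
          sc$displacement >= params$min_pursuit_displacement_px) {
        lab[vidx] <- "pursuit"
      }
    }
  }

  lab <- absorb_slivers(lab, dt, params$min_segment_ms)

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(
    participant_id = recording$participant_id,
    trial_id = recording$trial_id,
    label = r$values,
    t_start_ms = recording$t[starts],
    t_end_ms = recording$t[ends] + dt,
    stringsAsFactors = FALSE)
  seg$duration_ms <- seg$t_end_ms - seg$t_start_ms
  seg$mean_x <- seg$mean_y <- seg$score <- NA_real_
  for (k in seq_len(nrow(seg))) {
    idx <- starts[k]:ends[k]
    vidx <- idx[recording$valid[idx]]
    if (length(vidx)) {
      seg$mean_x[k] <- mean(recording$x[vidx])
      seg$mean_y[k] <- mean(recording$y[vidx])
    }
  }
  structure(seg,
            sample_labels = lab,
            trial_duration_ms = n * dt,
            class = c("event_segments", "data.frame"))
}

#' Quality-control filter on trials and participants
#'
#' A trial is removed when strictly more than half of its valid samples
#' exceed the saccade velocity threshold (noisy recording); a participant
#' is excluded when strictly more than half of their trials are removed.
#'
#' @param recordings_by_participant Named list (participant id) of lists of
#'   [gaze_recording()]s.
#' @inheritParams compute_velocity
#' @return A list with `kept` (same nested structure, surviving trials of
#'   surviving participants), `removed_trials` (data.frame with
#'   `participant_id`, `trial_id`, `frac_supra`) and
#'   `excluded_participants` (character).
#' @export
qc_filter <- function(recordings_by_participant, geometry,
                      params = parser_params()) {
  removed <- data.frame(participant_id = character(0),
                        trial_id = character(0), frac_supra = numeric(0))
  kept <- list()
  excluded <- character(0)
  for (pid in names(recordings_by_participant)) {
    recs <- recordings_by_participant[[pid]]
    keep_flags <- logical(length(recs))
    fracs <- numeric(length(recs))
    for (j in seq_along(recs)) {
      tr <- compute_velocity(recs[[j]], geometry, params)
      sp <- tr$speed[recs[[j]]$valid]
      fracs[j] <- sum(sp > params$saccade_vel_thresh, na.rm = TRUE) /
        length(sp)
      keep_flags[j] <- !(fracs[j] > 0.5)
    }
    if (any(!keep_flags)) {
      removed <- rbind(removed, data.frame(
        participant_id = pid,
        trial_id = vapply(recs[!keep_flags], `[[`, "", "trial_id"),
        frac_supra = fracs[!keep_flags]))
    }
    if (mean(!keep_flags) > 0.5) {
      excluded <- c(excluded, pid)
    } else {
      kept[[pid]] <- recs[keep_flags]
    }
  }
  list(kept = kept, removed_trials = removed,
       excluded_participants = excluded)
}

#' Summarise parsed events of one trial
#'
#' Per event type: number of segments, total time in ms and proportion of
#' the trial duration.
#'
#' @param segments Event segments from [parse_trial()].
#' @param trial_duration_ms Trial duration in ms; defaults to the
#'   attribute stored by [parse_trial()].
#' @return A data.frame with one row per label (`fixation`, `pursuit`,
#'   `saccade`, `missing`) and columns `count`, `total_ms`, `proportion`.
#' @export
summarize_events <- function(segments,
                             trial_duration_ms =
                               attr(segments, "trial_duration_ms")) {
  labels <- c("fixation", "pursuit", "saccade", "missing")
  out <- data.frame(label = labels, count = 0L, total_ms = 0,
                    proportion = 0)
  if (nrow(segments)) {
    agg_n <- table(factor(segments$label, levels = labels))
    agg_ms <- tapply(segments$duration_ms,
                     factor(segments$label, levels = labels), sum)
    out$count <- as.integer(agg_n)
    out$total_ms <- ifelse(is.na(agg_ms), 0, agg_ms)
    if (!is.null(trial_duration_ms) && trial_duration_ms > 0) {
      out$proportion <- out$total_ms / trial_duration_ms
    }
  }
  out
}
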