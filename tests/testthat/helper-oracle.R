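# Direct one-pass reference implementation of the event parser, written as
# plain sample-by-sample loops with stats::lm for the polynomial fits.
# Used to cross-check segment boundaries from the vectorised pipeline.

oracle_score <- function(t, x, y, params) {
  deg <- params$poly_degree
  tc <- (t - mean(t)) / 1000
  fit2 <- function(keep) {
    fx <- stats::lm(x ~ poly(tc, deg, raw = TRUE), subset = keep)
    fy <- stats::lm(y ~ poly(tc, deg, raw = TRUE), subset = keep)
    list(fx = fx, fy = fy,
         r = sqrt(stats::resid(fx)^2 + stats::resid(fy)^2))
  }
  f <- fit2(rep(TRUE, length(tc)))
  s <- stats::mad(f$r)
  keep <- if (s > 0) abs(f$r - stats::median(f$r)) <= 3 * s else
    rep(TRUE, length(f$r))
  if (sum(keep) >= deg + 2 && !all(keep)) f <- fit2(keep)
  else keep <- rep(TRUE, length(tc))
  rmse <- sqrt(mean(c(stats::resid(f$fx), stats::resid(f$fy))^2))
  # chord-sum arc length of the fitted curve on a dense grid
  g <- seq(min(tc[keep]), max(tc[keep]), length.out = 2000)
  px <- stats::predict(f$fx, newdata = data.frame(tc = g))
  py <- stats::predict(f$fy, newdata = data.frame(tc = g))
  arc <- sum(sqrt(diff(px)^2 + diff(py)^2))
  disp <- sqrt((px[length(px)] - px[1])^2 + (py[length(py)] - py[1])^2)
  list(score = rmse * exp(-arc), displacement = disp)
}

oracle_labels <- function(rec, geom, params = parser_params()) {
  n <- length(rec$t)
  dt <- 1000 / rec$rate_hz
  dpp_h <- degrees_per_pixel(geom, "horizontal")
  dpp_v <- degrees_per_pixel(geom, "vertical")
  sp <- rep(NA_real_, n)
  for (i in seq(2, n - 1)) {
    if (rec$valid[i] && rec$valid[i - 1] && rec$valid[i + 1]) {
      d <- rec$t[i + 1] - rec$t[i - 1]
      vx <- (rec$x[i + 1] - rec$x[i - 1]) / d * dpp_h
      vy <- (rec$y[i + 1] - rec$y[i - 1]) / d * dpp_v
      sp[i] <- sqrt(vx^2 + vy^2) * 1000
    }
  }
  w <- max(1L, as.integer(round(params$vel_window_ms / dt)))
  half <- w %/% 2L
  sm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(sp[i])) {
      win <- sp[max(1, i - half):min(n, i + half)]
      sm[i] <- mean(win, na.rm = TRUE)
    }
  }
  lab <- ifelse(rec$valid, "fixation", "missing")
  lab[!is.na(sm) & sm > params$saccade_vel_thresh] <- "saccade"
  # candidate smooth runs, scanned sample by sample
  i <- 1
  while (i <= n) {
    if (!is.na(sm[i]) && sm[i] <= params$pursuit_vel_max &&
        lab[i] != "saccade") {
      j <- i
      while (j < n && !is.na(sm[j + 1]) &&
             sm[j + 1] <= params$pursuit_vel_max &&
             lab[j + 1] != "saccade") j <- j + 1
      if ((j - i + 1) * dt >= params$pursuit_min_dur_ms) {
        idx <- i:j
        if (length(idx) >= params$poly_degree + 2) {
          sc <- oracle_score(rec$t[idx], rec$x[idx], rec$y[idx], params)
          if (sc$score < params$score_thresh &&
              sc$displacement >= params$min_pursuit_displacement_px) {
            lab[idx] <- "pursuit"
          }
        }
      }
      i <- j + 1
    } else i <- i + 1
  }
  # absorb short transition slivers into the longer neighbour
  repeat {
    r <- rle(lab)
    k <- length(r$lengths)
    changed <- FALSE
    for (q in seq_len(k)) {
      if (r$values[q] == "missing" || r$lengths[q] * dt >= params$min_segment_ms) next
      left <- if (q > 1 && r$values[q - 1] != "missing") q - 1 else NA
      right <- if (q < k && r$values[q + 1] != "missing") q + 1 else NA
      pick <- if (is.na(left)) right
      else if (is.na(right)) left
      else if (r$lengths[left] >= r$lengths[right]) left else right
      if (!is.na(pick) && r$values[pick] != r$values[q]) {
        r$values[q] <- r$values[pick]
        changed <- TRUE
      }
    }
    if (!changed) break
    lab <- inverse.rle(r)
  }
  lab
}
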