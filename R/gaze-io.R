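#' Construct and validate a gaze recording
#'
#' A gaze recording is one trial's raw sample stream: timestamps in ms,
#' screen coordinates in pixels (0-based, origin top-left) and a per-sample
#' validity flag (`FALSE` marks blinks / track loss). Invalid samples keep
#' their last coordinates for bookkeeping but are ignored by all downstream
#' computation.
#'
#' @param participant_id,trial_id Identifiers (coerced to character).
#' @param t Numeric vector of strictly increasing timestamps in ms.
#' @param x,y Numeric screen coordinates in pixels.
#' @param valid Logical vector; `FALSE` = blink or track loss.
#' @param rate_hz Sampling rate in Hz (default 1000).
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, trial_id, t, x, y,
                           valid = rep(TRUE, length(t)), rate_hz = 1000) {
  n <- length(t)
  if (length(x) != n || length(y) != n || length(valid) != n) {
    stop("gaze_recording: t, x, y, valid must have equal length")
  }
  if (n > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop(sprintf("gaze_recording: timestamps not strictly increasing at row %d",
                   bad[1] + 1))
    }
  }
  valid <- as.logical(valid)
  if (anyNA(valid)) stop("gaze_recording: valid flags must be TRUE/FALSE")
  if (any(!is.finite(x[valid])) || any(!is.finite(y[valid]))) {
    stop("gaze_recording: coordinates of valid samples must be finite")
  }
  structure(
    list(participant_id = as.character(participant_id),
         trial_id = as.character(trial_id),
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         valid = valid, rate_hz = rate_hz),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s / %s: %d samples at %g Hz, %.1f%% valid\n",
              x$participant_id, x$trial_id, length(x$t), x$rate_hz,
              100 * mean(x$valid)))
  invisible(x)
}

#' Read / write gaze samples as CSV
#'
#' The sample CSV dialect is `t,x,y,valid` with a header row; `valid` is
#' 0/1. Timestamps must be strictly increasing.
#'
#' @param path File path.
#' @param participant_id,trial_id Identifiers attached to the recording.
#' @param rate_hz Sampling rate in Hz.
#' @return `read_gaze_csv` returns a [gaze_recording()];
#'   `write_gaze_csv` returns `path` invisibly.
#' @export
read_gaze_csv <- function(path, participant_id = "unknown",
                          trial_id = "unknown", rate_hz = 1000) {
  if (!file.exists(path)) stop("read_gaze_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "valid")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("read_gaze_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  gaze_recording(participant_id, trial_id, df$t, df$x, df$y,
                 valid = df$valid != 0, rate_hz = rate_hz)
}

#' @rdname read_gaze_csv
#' @param recording A [gaze_recording()].
#' @export
write_gaze_csv <- function(recording, path) {
  df <- data.frame(t = recording$t, x = recording$x, y = recording$y,
                   valid = as.integer(recording$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write oculomotor event segments as TSV
#'
#' Event segments are stored as tab-separated rows with columns
#' `participant_id, trial_id, label, t_start_ms, t_end_ms, duration_ms,
#' mean_x, mean_y, score`. Segments must be time-sorted and non-overlapping within each
#' trial (half-open intervals `[t_start, t_end)`).
#'
#' @param segments A data.frame of event segments as produced by
#'   [parse_trial()].
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the segments data.frame.
#' @export
write_events_tsv <- function(segments, path) {
  segments <- as.data.frame(segments)
  cols <- c("participant_id", "trial_id", "label", "t_start_ms", "t_end_ms",
            "duration_ms", "mean_x", "mean_y", "score")
  if (nrow(segments)) {
    if (is.null(segments$participant_id)) segments$participant_id <- "unknown"
    key <- paste(segments$participant_id, segments$trial_id)
    for (id in unique(key)) {
      s <- segments[key == id, ]
      s <- s[order(s$t_start_ms), ]
      if (nrow(s) > 1 && any(s$t_start_ms[-1] < s$t_end_ms[-nrow(s)])) {
        stop("write_events_tsv: overlapping segments in trial ", id)
      }
    }
    out <- segments[, cols]
  } else {
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("participant_id", "trial_id")) {
    if (!is.null(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  df
}

#' Read / write per-trial metadata as CSV
#'
#' Columns: `trial_id, pedestrian_present, n_vehicles` and optionally
#' `density_class` (`low`/`high`). Pedestrian presence is dichotomous.
#'
#' @param metadata Data.frame of trial metadata.
#' @param path File path.
#' @export
write_metadata_csv <- function(metadata, path) {
  stopifnot(all(c("trial_id", "pedestrian_present", "n_vehicles") %in%
                  names(metadata)))
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trial_id = "character"))
  if (!all(df$pedestrian_present %in% c(0, 1))) {
    stop("read_metadata_csv: pedestrian_present must be 0/1")
  }
  if (any(df$n_vehicles < 0)) stop("read_metadata_csv: negative n_vehicles")
  df
}

#' Read / write crossing-decision records as CSV
#'
#' One row per participant x trial with the number of button presses and
#' the press durations in ms (semicolon-separated in the file). The
#' duration list length always equals `n_presses`.
#'
#' @param decisions Data.frame with `participant_id, trial_id, n_presses`
#'   and a list-column `press_durations_ms`.
#' @param path File path.
#' @export
write_decisions_csv <- function(decisions, path) {
  stopifnot(all(lengths(decisions$press_durations_ms) == decisions$n_presses))
  df <- data.frame(
    participant_id = decisions$participant_id,
    trial_id = decisions$trial_id,
    n_presses = decisions$n_presses,
    press_durations_ms = vapply(
      decisions$press_durations_ms,
      function(d) paste(format(d, trim = TRUE, scientific = FALSE),
                        collapse = ";"),
      character(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decisions_csv
#' @export
read_decisions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trial_id = "character",
                                       participant_id = "character"))
  df$press_durations_ms <- lapply(df$press_durations_ms, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  if (!all(lengths(df$press_durations_ms) == df$n_presses)) {
    stop("read_decisions_csv: press duration count does not match n_presses")
  }
  df
}

#' Read / write a labelled numeric matrix as plain text
#'
#' Tab-separated with row and column labels; used for gaze similarity
#' matrices.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_txt <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}
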