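# Row/column Gaussian convolution matrix with renormalised (mass
# preserving) truncated kernels, so map intensity is not suppressed at the
# borders.
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * sigma^2))
  K[abs(d) > 4 * sigma] <- 0
  K / rowSums(K)
}

#' Smoothed, z-scored gaze-density map of one trial
#'
#' Valid gaze sample positions are accumulated into a (optionally
#' downsampled) screen-resolution grid, convolved with an isotropic
#' Gaussian whose SD is `sigma_deg` degrees of visual angle (converted to
#' pixels per axis through the screen geometry), and finally z-scored over
#' all grid cells.
#'
#' @param samples A [gaze_recording()] or a data.frame/list with `x`, `y`
#'   in screen pixels (invalid samples of a recording are ignored).
#' @param geometry A [screen_geometry()].
#' @param sigma_deg Smoothing SD in degrees of visual angle (default 1).
#' @param downsample Integer downsampling factor of the screen grid
#'   (default 4); pairwise map correlations are essentially invariant to
#'   modest downsampling because the smoothing kernel spans many cells.
#'
#' @return A `gaze_map`: a numeric matrix (rows = vertical axis) with mean
#'   0 and SD 1, carrying attributes `sigma_deg`, `downsample` and
#'   `z_scored`.
#' @export
build_gaze_map <- function(samples, geometry, sigma_deg = 1,
                           downsample = 4) {
  if (inherits(samples, "gaze_recording")) {
    x <- samples$x[samples$valid]
    y <- samples$y[samples$valid]
  } else {
    x <- samples$x
    y <- samples$y
  }
  if (!length(x)) stop("build_gaze_map: no valid samples")
  H <- ceiling(geometry$height_px / downsample)
  W <- ceiling(geometry$width_px / downsample)
  ix <- pmin(pmax(floor(x / downsample) + 1, 1), W)
  iy <- pmin(pmax(floor(y / downsample) + 1, 1), H)
  m <- matrix(tabulate((ix - 1) * H + iy, nbins = H * W), H, W)

  sig_v <- sigma_deg / degrees_per_pixel(geometry, "vertical") / downsample
  sig_h <- sigma_deg / degrees_per_pixel(geometry, "horizontal") / downsample
  m <- gauss_conv_matrix(H, sig_v) %*% m %*%
    t(gauss_conv_matrix(W, sig_h))

  s <- stats::sd(m)
  if (s == 0) stop("build_gaze_map: degenerate (constant) map")
  m <- (m - mean(m)) / s
  structure(m, sigma_deg = sigma_deg, downsample = downsample,
            z_scored = TRUE, class = c("gaze_map", "matrix", "array"))
}

#' Gaze similarity matrix (GSM)
#'
#' Pairwise Pearson correlations between flattened gaze maps, Fisher
#' z-transformed. Correlations are clipped at |r| = 1 - 1e-6 so duplicate
#' maps map to a finite z. The diagonal is excluded from all summaries.
#'
#' @param maps List of `gaze_map`s on identical grids; names are used as
#'   trial ids.
#' @return A symmetric `similarity_matrix` (n_trials x n_trials) of
#'   Fisher-z correlations.
#' @export
similarity_matrix <- function(maps) {
  if (length(maps) < 2) stop("similarity_matrix: need at least 2 maps")
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("similarity_matrix: maps must share one grid shape")
  }
  M <- vapply(maps, as.vector, numeric(length(maps[[1]])))
  r <- stats::cor(M)
  cap <- 1 - 1e-6
  z <- atanh(pmin(pmax(r, -cap), cap))
  ids <- names(maps)
  if (is.null(ids)) ids <- sprintf("trial%03d", seq_along(maps))
  dimnames(z) <- list(ids, ids)
  structure(z, class = c("similarity_matrix", "matrix", "array"))
}

# per-trial mean Fisher z to all other trials
mean_offdiag <- function(z) {
  n <- ncol(z)
  (rowSums(z) - diag(z)) / (n - 1)
}

#' Group similarity curve with participant-level bootstrap CIs
#'
#' For each participant, the mean Fisher-z similarity of each trial's gaze
#' map to all other trials; the group curve is the across-participant mean
#' per trial, sorted descending, with percentile-bootstrap confidence
#' intervals obtained by resampling participants.
#'
#' @param matrices_by_participant List (one per participant) of
#'   `similarity_matrix` objects over the same trial set.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A data.frame of class `similarity_curve` with columns
#'   `trial_id`, `mean_z`, `lower`, `upper`, sorted by `mean_z`
#'   descending.
#' @export
similarity_curve <- function(matrices_by_participant, n_boot = 1000,
                             seed = 1, conf = 0.95) {
  stopifnot(n_boot >= 1)
  ids <- colnames(matrices_by_participant[[1]])
  for (m in matrices_by_participant) {
    if (!identical(colnames(m), ids)) {
      stop("similarity_curve: participants must share one trial set")
    }
  }
  P <- length(matrices_by_participant)
  per_part <- t(vapply(matrices_by_participant, mean_offdiag,
                       numeric(length(ids))))        # P x n_trials
  est <- colMeans(per_part)

  if (P == 1) {
    warning("similarity_curve: single participant; CIs degenerate to the estimate")
    lower <- upper <- est
  } else {
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, length(ids))
    for (b in seq_len(n_boot)) {
      boots[b, ] <- colMeans(per_part[sample(P, P, replace = TRUE), ,
                                      drop = FALSE])
    }
    a <- (1 - conf) / 2
    qs <- apply(boots, 2, stats::quantile, probs = c(a, 1 - a),
                names = FALSE)
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  ord <- order(est, decreasing = TRUE)
  structure(data.frame(trial_id = ids[ord], mean_z = est[ord],
                       lower = lower[ord], upper = upper[ord],
                       stringsAsFactors = FALSE),
            class = c("similarity_curve", "data.frame"))
}
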