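# connected-component labelling; EBImage::bwlabel is 4-connectivity, the
# 8-connectivity variant merges labels that touch diagonally
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1)
  if (connectivity == 4 || max(lab) < 2) return(lab)
  H <- nrow(lab)
  W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(max(lab))),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- comp[as.character(seq_len(max(lab)))]
  remap <- match(remap, sort(unique(remap)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

new_mog_state <- function(frame, n_components, learning_rate,
                          init_var = 0.01) {
  npix <- length(frame)
  w <- matrix(0, n_components, npix)
  mu <- matrix(0, n_components, npix)
  v <- matrix(init_var, n_components, npix)
  w[1, ] <- 1
  mu[1, ] <- as.vector(frame)
  list(w = w, mu = mu, var = v, K = n_components,
       learning_rate = learning_rate, init_var = init_var,
       dim = dim(frame), n_frames = 1L, bg_weight = 0.6)
}

mog_update <- function(model, frame) {
  x <- as.vector(frame)
  K <- model$K
  a <- model$learning_rate
  d2 <- sweep(-model$mu, 2, x, `+`)^2            # (x - mu)^2, K x npix
  matched <- d2 <= 6.25 * model$var & model$w > 0
  score <- ifelse(matched, model$w / sqrt(model$var), -Inf)
  m <- max.col(t(score), ties.method = "first")  # winning component
  none <- !matched[cbind(m, seq_along(x))]

  hit <- matrix(FALSE, K, length(x))
  hit[cbind(m[!none], which(!none))] <- TRUE
  model$w <- (1 - a) * model$w + a * hit
  rho <- a
  dm <- sweep(-model$mu, 2, x, `+`)              # x - mu
  model$mu <- model$mu + rho * dm * hit
  dm2 <- sweep(-model$mu, 2, x, `+`)^2
  model$var <- ifelse(hit, (1 - rho) * model$var + rho * dm2, model$var)
  model$var <- pmax(model$var, 1e-4)

  if (any(none)) {
    j <- which(none)
    worst <- max.col(t(-model$w[, j, drop = FALSE]), ties.method = "first")
    idx <- cbind(worst, j)
    model$mu[idx] <- x[j]
    model$var[idx] <- model$init_var
    model$w[idx] <- 0.05
  }
  model$w <- sweep(model$w, 2, colSums(model$w), `/`)
  model$n_frames <- model$n_frames + 1L
  model
}

#' Fit a per-pixel Gaussian-mixture background model
#'
#' Online Stauffer-Grimson style update over the frame stack: each pixel
#' keeps a mixture of up to `n_components` Gaussians over intensity; the
#' observed value updates the best-matching component (within 2.5 SDs) or
#' replaces the weakest one. High-weight, low-variance components form the
#' background.
#'
#' @param frames Array `height x width x n_frames`, intensities in
#'   \[0, 1\]; at least 10 frames are recommended for a stable estimate.
#' @param n_components Gaussians per pixel (default 3).
#' @param learning_rate Online update rate (default 0.02); kept low so
#'   that pixels repeatedly crossed by successive vehicles do not absorb
#'   the vehicle intensity into the background.
#' @return A `background_model` list with per-pixel weights, means and
#'   variances (weights sum to 1 at every pixel).
#' @export
fit_background <- function(frames, n_components = 3, learning_rate = 0.02) {
  stopifnot(length(dim(frames)) == 3)
  Tn <- dim(frames)[3]
  if (Tn < 2) stop("fit_background: need at least 2 frames")
  model <- new_mog_state(frames[, , 1], n_components, learning_rate)
  for (f in 2:Tn) model <- mog_update(model, frames[, , f])
  class(model) <- "background_model"
  model
}

#' Foreground mask of a frame under a background model
#'
#' Background components at each pixel are the highest-ranked (weight over
#' SD) components whose cumulative weight reaches the background fraction;
#' a pixel is foreground when its value matches none of them within 2.5
#' SDs.
#'
#' @param frame Matrix `height x width`.
#' @param model A `background_model`.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
foreground_mask <- function(frame, model) {
  x <- as.vector(frame)
  K <- model$K
  score <- t(model$w / sqrt(model$var))          # npix x K
  npix <- length(x)
  ordk <- matrix(0L, npix, K)
  s <- score
  for (j in seq_len(K)) {
    ordk[, j] <- max.col(s, ties.method = "first")
    s[cbind(seq_len(npix), ordk[, j])] <- -Inf
  }
  wt <- t(model$w)
  cum <- matrix(0, npix, K)
  acc <- numeric(npix)
  is_bg <- matrix(FALSE, npix, K)
  for (j in seq_len(K)) {
    sel <- cbind(seq_len(npix), ordk[, j])
    is_bg[sel] <- j == 1 | acc < model$bg_weight
    acc <- acc + wt[sel]
  }
  d2 <- sweep(-model$mu, 2, x, `+`)^2
  match_bg <- d2 <= 6.25 * model$var & t(is_bg) & model$w > 0
  fg <- colSums(match_bg) == 0
  matrix(fg, model$dim[1], model$dim[2])
}

#' Count moving objects in a frame (blob analysis)
#'
#' Thresholded foreground, 3x3 morphological opening, 8-connected
#' component labelling, and a minimum-area filter. Objects merged by
#' contact are counted once.
#'
#' @param frame Matrix `height x width`.
#' @param model A `background_model`.
#' @param min_area_px Minimum blob area in pixels (default 40).
#' @return Integer count.
#' @export
count_moving_objects <- function(frame, model, min_area_px = 40) {
  mask <- foreground_mask(frame, model)
  opened <- EBImage::opening(mask * 1, EBImage::makeBrush(3, "box"))
  lab <- label_components(opened > 0, connectivity = 8)
  if (max(lab) == 0) return(0L)
  sum(tabulate(lab[lab > 0], nbins = max(lab)) >= min_area_px)
}

#' Per-trial traffic density from per-frame counts
#'
#' The trial's vehicle count is the maximum simultaneous on-screen count,
#' matching the dichotomisation of dense traffic as more than three
#' vehicles on screen.
#'
#' @param frame_counts Integer per-frame object counts.
#' @return Maximum count.
#' @export
trial_density <- function(frame_counts) {
  if (!length(frame_counts)) stop("trial_density: need at least one count")
  max(frame_counts)
}

#' Online per-frame vehicle counts for a frame stack
#'
#' Single pass over the video: each frame is classified against the
#' background model state before being used to update it; frames before
#' `skip` (model burn-in) are not counted.
#'
#' @inheritParams fit_background
#' @param min_area_px Minimum blob area in pixels.
#' @param skip Number of leading frames used only to initialise the model.
#' @return A list with `counts` (one per counted frame), `n_vehicles`
#'   (their maximum) and the final `model`.
#' @export
count_trial_vehicles <- function(frames, n_components = 3,
                                 learning_rate = 0.02, min_area_px = 40,
                                 skip = 10) {
  Tn <- dim(frames)[3]
  if (Tn < 2) stop("count_trial_vehicles: need at least 2 frames")
  model <- new_mog_state(frames[, , 1], n_components, learning_rate)
  counts <- integer(0)
  for (f in 2:Tn) {
    if (f > skip) {
      counts <- c(counts,
                  count_moving_objects(frames[, , f], model, min_area_px))
    }
    model <- mog_update(model, frames[, , f])
  }
  class(model) <- "background_model"
  list(counts = counts, n_vehicles = trial_density(counts), model = model)
}
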