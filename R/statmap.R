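# Shared preparation for pixel-wise fitting: average maps within
# participant x condition cells and build the full/reduced design matrices
# for the requested term.
prepare_statmap <- function(maps, design, effect) {
  stopifnot(length(maps) == nrow(design))
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("prepare_statmap: maps must share one grid shape")
  }
  factors <- setdiff(names(design), c("participant_id", "stimulus_id"))
  if (!length(factors)) stop("prepare_statmap: no factor columns in design")
  for (f in factors) design[[f]] <- factor(design[[f]])
  if (any(vapply(design[factors], nlevels, 0L) < 2)) {
    stop("prepare_statmap: every tested factor needs >= 2 levels")
  }

  terms <- factors
  if (grepl(":", effect, fixed = TRUE)) terms <- c(terms, effect)
  if (!effect %in% terms) {
    stop("prepare_statmap: unknown effect '", effect, "'")
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))

  cond_key <- do.call(paste, c(design[factors], sep = "|"))
  cell_key <- paste(design$participant_id, cond_key, sep = "@")

  M <- vapply(maps, as.vector, numeric(prod(dims[[1]])))  # npix x nmaps
  Ysum <- rowsum(t(M), cell_key)                          # ncell x npix
  counts <- as.vector(table(cell_key)[rownames(Ysum)])
  Y <- Ysum / counts

  first <- match(rownames(Ysum), cell_key)
  cell_design <- design[first, c("participant_id", factors), drop = FALSE]
  ord <- order(cell_design$participant_id, cond_key[first])
  Y <- Y[ord, , drop = FALSE]
  cell_design <- cell_design[ord, , drop = FALSE]
  rownames(cell_design) <- NULL

  X <- stats::model.matrix(fml, cell_design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("prepare_statmap: rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  term_labels <- attr(stats::terms(fml), "term.labels")
  eff_cols <- which(attr(X, "assign") == match(effect, term_labels))
  if (!length(eff_cols)) stop("prepare_statmap: effect has no columns")
  Xr <- X[, -eff_cols, drop = FALSE]

  list(Y = Y, cell_design = cell_design, X = X, Xr = Xr,
       eff_cols = eff_cols, grid_dim = dims[[1]],
       downsample = attr(maps[[1]], "downsample") %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# F map for response matrix Y (n x npix) given precomputed orthonormal
# bases of the full and reduced design column spaces
fmap_from_bases <- function(Y, Qf, Qr, df1, df2) {
  tot <- colSums(Y^2)
  rss_f <- tot - colSums((crossprod(Qf, Y))^2)
  rss_r <- tot - colSums((crossprod(Qr, Y))^2)
  num <- pmax(rss_r - rss_f, 0)
  # residuals indistinguishable from exact fit (relative to the response
  # scale) are treated as zero to avoid 0/0 noise ratios
  scale <- pmax(tot, 1e-300)
  zero_f <- rss_f <= 1e-12 * scale
  ifelse(!zero_f,
         (num / df1) / (rss_f / df2),
         ifelse(num > 1e-12 * scale, Inf, 0))
}

#' Pixel-wise linear-model fit of gaze maps over a design (uncorrected)
#'
#' Two-stage summary-statistics approximation of a pixel-wise linear mixed
#' model: gaze maps are first averaged within participant x condition
#' cells (absorbing the subject random intercept and stimulus variation),
#' then an ordinary linear model with the design's fixed effects is fitted
#' at every grid cell, returning coefficient maps and the F map for the
#' requested term.
#'
#' @param maps List of `gaze_map`s (one per row of `design`).
#' @param design Data.frame with `participant_id`, optional `stimulus_id`
#'   and experimental factor columns (e.g. `age_group`,
#'   `pedestrian_present`, `density_class`).
#' @param effect The term to test: a factor name or an interaction such as
#'   `"age_group:pedestrian_present"` (interactions are added to the model
#'   when requested).
#' @return A `stat_map`: list with the F grid (`F`), effect coefficient
#'   grids (`coef`), degrees of freedom, and empty significance slots to
#'   be filled by [cluster_bootstrap_correct()].
#' @export
pixelwise_fit <- function(maps, design, effect) {
  prep <- prepare_statmap(maps, design, effect)
  qf_ <- qr(prep$X)
  Qf <- qr.Q(qf_)
  Qr <- qr.Q(qr(prep$Xr))
  df1 <- length(prep$eff_cols)
  df2 <- nrow(prep$X) - ncol(prep$X)
  if (df2 <= 0) stop("pixelwise_fit: no residual degrees of freedom")

  Fv <- fmap_from_bases(prep$Y, Qf, Qr, df1, df2)
  B <- qr.coef(qf_, prep$Y)                      # p x npix
  coef_maps <- lapply(prep$eff_cols, function(j) {
    matrix(B[j, ], prep$grid_dim[1], prep$grid_dim[2])
  })
  names(coef_maps) <- colnames(prep$X)[prep$eff_cols]

  structure(list(F = matrix(Fv, prep$grid_dim[1], prep$grid_dim[2]),
                 coef = coef_maps, effect = effect, df1 = df1, df2 = df2,
                 mask = NULL, clusters = NULL, cluster_thresh = NULL,
                 downsample = prep$downsample, grid_dim = prep$grid_dim),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> effect '%s': F(%d, %d), grid %d x %d\n",
              x$effect, x$df1, x$df2, x$grid_dim[1], x$grid_dim[2]))
  if (!is.null(x$mask)) {
    cat(sprintf("  corrected: %d significant cluster(s), %d cells (%d px at full resolution)\n",
                if (is.null(x$clusters)) 0L else nrow(x$clusters),
                sum(x$mask), significant_area(x)))
  }
  invisible(x)
}

cluster_masses <- function(Fgrid, thresh) {
  mask <- Fgrid > thresh
  if (!any(mask)) {
    return(list(labels = NULL,
                stats = data.frame(cluster = integer(0),
                                   size_cells = integer(0),
                                   mass = numeric(0))))
  }
  lab <- EBImage::bwlabel(mask * 1)
  ids <- seq_len(max(lab))
  mass <- as.vector(rowsum(Fgrid[lab > 0], lab[lab > 0]))
  size <- tabulate(lab[lab > 0], nbins = max(lab))
  list(labels = lab,
       stats = data.frame(cluster = ids, size_cells = size, mass = mass))
}

#' Bootstrap cluster correction of a pixel-wise statistical map
#'
#' Multiple-comparison control by cluster mass: the cluster-forming
#' threshold is the pointwise `1 - alpha` F quantile; the null
#' distribution of the maximum cluster mass is built from `n_boot`
#' resamples in which whole participants' residual maps (residuals of the
#' full model, mapped cell-by-cell) are resampled with replacement and
#' added to the reduced-model (effect-removed) fit. Observed clusters
#' whose mass exceeds the null `1 - alpha` quantile are retained.
#'
#' @param statmap A `stat_map` from [pixelwise_fit()].
#' @inheritParams pixelwise_fit
#' @param alpha Significance level (default 0.05).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return The `stat_map` with `mask` (logical grid), `clusters`
#'   (data.frame with sizes, masses and bootstrap p values) and
#'   `cluster_thresh` filled in.
#' @export
cluster_bootstrap_correct <- function(statmap, maps, design,
                                      alpha = 0.05, n_boot = 200,
                                      seed = 1) {
  if (n_boot < 100) {
    stop("cluster_bootstrap_correct: n_boot must be >= 100 for alpha resolution")
  }
  prep <- prepare_statmap(maps, design, statmap$effect)
  df1 <- length(prep$eff_cols)
  df2 <- nrow(prep$X) - ncol(prep$X)
  Qf <- qr.Q(qr(prep$X))
  Qr <- qr.Q(qr(prep$Xr))
  thresh <- stats::qf(1 - alpha, df1, df2)

  obs <- cluster_masses(statmap$F, thresh)

  # residuals of the full model; reduced-model fit is the null surface
  R <- prep$Y - Qf %*% crossprod(Qf, prep$Y)
  Yhat0 <- Qr %*% crossprod(Qr, prep$Y)

  pid <- prep$cell_design$participant_id
  parts <- unique(pid)
  rows_by_part <- lapply(parts, function(p) which(pid == p))
  ncell_per <- lengths(rows_by_part)
  if (length(unique(ncell_per)) != 1) {
    stop("cluster_bootstrap_correct: participants must share a complete condition-cell set")
  }

  set.seed(seed)
  null_max <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    donors <- sample(length(parts), length(parts), replace = TRUE)
    idx <- unlist(rows_by_part[donors], use.names = FALSE)
    Yb <- Yhat0 + R[idx, , drop = FALSE]
    Fb <- fmap_from_bases(Yb, Qf, Qr, df1, df2)
    cb <- cluster_masses(matrix(Fb, prep$grid_dim[1], prep$grid_dim[2]),
                         thresh)
    null_max[b] <- if (nrow(cb$stats)) max(cb$stats$mass) else 0
  }
  crit <- stats::quantile(null_max, 1 - alpha, names = FALSE)

  mask <- matrix(FALSE, prep$grid_dim[1], prep$grid_dim[2])
  clusters <- obs$stats
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$mass,
                         function(m) (1 + sum(null_max >= m)) / (1 + n_boot),
                         numeric(1))
    keep <- clusters$mass > crit
    for (id in clusters$cluster[keep]) mask[obs$labels == id] <- TRUE
    clusters <- clusters[keep, , drop = FALSE]
    rownames(clusters) <- NULL
  } else {
    clusters$p <- numeric(0)
  }
  statmap$mask <- mask
  statmap$clusters <- clusters
  statmap$cluster_thresh <- thresh
  statmap$null_max_mass <- null_max
  statmap
}

#' Signed contrast map between two groups
#'
#' Averages each participant's maps into one map, computes the per-pixel
#' two-sample t statistic for `group_a - group_b`, and applies the same
#' bootstrap cluster correction to the squared statistic. The `t` grid is
#' signed; the mask marks significant cells of either sign.
#'
#' @inheritParams pixelwise_fit
#' @param group_col Name of the grouping column in `design` (default
#'   `"age_group"`).
#' @param group_a,group_b Group labels to contrast.
#' @param alpha,n_boot,seed Passed to [cluster_bootstrap_correct()].
#' @return A `stat_map` with an additional signed `t` grid.
#' @export
contrast_map <- function(maps, design, group_a, group_b,
                         group_col = "age_group", alpha = 0.05,
                         n_boot = 200, seed = 1) {
  g <- as.character(design[[group_col]])
  if (!group_a %in% g) stop("contrast_map: unknown group '", group_a, "'")
  if (!group_b %in% g) stop("contrast_map: unknown group '", group_b, "'")

  collapse_group <- function(grp, tag) {
    sel <- which(g == grp)
    pid <- design$participant_id[sel]
    mm <- lapply(split(sel, pid), function(ii) {
      Reduce(`+`, maps[ii]) / length(ii)
    })
    list(maps = mm,
         design = data.frame(
           participant_id = paste0(tag, "_", names(mm)),
           contrast_group = tag, stringsAsFactors = FALSE))
  }
  a <- collapse_group(group_a, "A")
  b <- collapse_group(group_b, "B")
  maps2 <- c(a$maps, b$maps)
  for (i in seq_along(maps2)) {
    attr(maps2[[i]], "downsample") <- attr(maps[[1]], "downsample")
  }
  design2 <- rbind(a$design, b$design)

  sm <- pixelwise_fit(maps2, design2, "contrast_group")
  # model.matrix codes group B relative to A: beta_B = mean(B) - mean(A)
  sgn <- -sign(sm$coef[[1]])
  sgn[sm$coef[[1]] == 0] <- 0
  sm <- cluster_bootstrap_correct(sm, maps2, design2, alpha = alpha,
                                  n_boot = n_boot, seed = seed)
  sm$t <- sgn * sqrt(sm$F)
  sm$effect <- paste0(group_a, " - ", group_b)
  sm
}

#' Significant area of a corrected statistical map
#'
#' Number of significant cells, rescaled to full-resolution screen pixel
#' units (each grid cell covers `downsample^2` screen pixels).
#'
#' @param statmap A corrected `stat_map`.
#' @return Pixel count at full screen resolution.
#' @export
significant_area <- function(statmap) {
  if (is.null(statmap$mask)) stop("significant_area: run cluster correction first")
  sum(statmap$mask) * statmap$downsample^2
}
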