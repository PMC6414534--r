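#' k-means clustering with k-means++ seeding and restarts
#'
#' Lloyd's algorithm initialised by k-means++ probabilistic far-point
#' seeding, repeated `n_restarts` times; the solution with the lowest
#' within-cluster sum of squares wins (ties broken by the earliest
#' restart). Centroids are reported sorted ascending and assignments are
#' relabelled accordingly. Deterministic given `seed`.
#'
#' @param values Numeric vector of finite observations.
#' @param k Number of clusters (`k <= length(values)`).
#' @param n_restarts Number of independent restarts (default 1000).
#' @param seed Integer seed.
#' @return A list of class `kmeans_pp` with `k`, `centroids` (sorted),
#'   `assignments`, `wcss`, `n_restarts`, `seed`.
#' @export
kmeans_pp <- function(values, k, n_restarts = 1000, seed = 1) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < k) stop("kmeans_pp: need at least k observations")
  if (any(!is.finite(x))) stop("kmeans_pp: values must be finite")
  set.seed(seed)

  seed_pp <- function() {
    centres <- numeric(k)
    centres[1] <- x[sample.int(n, 1)]
    if (k > 1) {
      d2 <- (x - centres[1])^2
      for (j in 2:k) {
        centres[j] <- if (sum(d2) > 0) {
          x[sample.int(n, 1, prob = d2)]
        } else x[sample.int(n, 1)]
        d2 <- pmin(d2, (x - centres[j])^2)
      }
    }
    centres
  }

  lloyd <- function(centres, max_iter = 100) {
    assign_old <- integer(n)
    for (it in seq_len(max_iter)) {
      D <- abs(outer(x, centres, `-`))
      a <- max.col(-D, ties.method = "first")
      for (j in seq_len(k)) {
        xj <- x[a == j]
        if (length(xj)) centres[j] <- mean(xj)
        else centres[j] <- x[which.max(apply(D, 1, min))]  # revive empty
      }
      if (identical(a, assign_old)) break
      assign_old <- a
    }
    wcss <- sum((x - centres[a])^2)
    list(centres = centres, assignments = a, wcss = wcss)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd(seed_pp())
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  ord <- order(best$centres)
  structure(list(k = k, centroids = best$centres[ord],
                 assignments = match(best$assignments, ord),
                 wcss = best$wcss, n_restarts = n_restarts, seed = seed),
            class = "kmeans_pp")
}

#' @export
print.kmeans_pp <- function(x, ...) {
  cat(sprintf("<kmeans_pp> k = %d, WCSS = %.4g (%d restarts)\n centroids: %s\n",
              x$k, x$wcss, x$n_restarts,
              paste(signif(x$centroids, 4), collapse = ", ")))
  invisible(x)
}

winsorize <- function(x, g) {
  xs <- sort(x)
  n <- length(x)
  lo <- xs[g + 1]
  hi <- xs[n - g]
  pmin(pmax(x, lo), hi)
}

trimmed_mean <- function(x, trim) mean(x, trim = trim)

# consistency constant of the winsorized variance under normality
winvar_const <- function(trim) {
  if (trim == 0) return(1)
  q <- stats::qnorm(1 - trim)
  (1 - 2 * trim) - 2 * q * stats::dnorm(q) + 2 * trim * q^2
}

#' Yuen's two-sample test on trimmed means
#'
#' Robust location comparison using `trim`-trimmed means with winsorized
#' variances and Welch-Satterthwaite degrees of freedom. With `trim = 0`
#' it reduces exactly to Welch's t test. The effect size is the
#' explanatory (xi-type) robust measure: the square root of the variance
#' explained by the trimmed group means relative to the
#' winsorized-variance estimate of the total variance, signed by the
#' direction of the difference.
#'
#' @param x,y Numeric samples.
#' @param trim Trim proportion in `[0, 0.5)` (default 0.2).
#' @param alpha Level used for the reported confidence interval.
#' @return A list of class `yuen_test` with `statistic`, `df`, `p.value`,
#'   `effect_size`, `trim`, `trimmed_means`, `conf.int`.
#' @export
yuen_test <- function(x, y, trim = 0.2, alpha = 0.05) {
  if (trim < 0 || trim >= 0.5) stop("yuen_test: trim must be in [0, 0.5)")
  n1 <- length(x)
  n2 <- length(y)
  g1 <- floor(trim * n1)
  g2 <- floor(trim * n2)
  h1 <- n1 - 2 * g1
  h2 <- n2 - 2 * g2
  if (h1 < 2 || h2 < 2) stop("yuen_test: excessive trim for sample size")

  tm1 <- trimmed_mean(x, trim)
  tm2 <- trimmed_mean(y, trim)
  sw1 <- stats::var(winsorize(x, g1))
  sw2 <- stats::var(winsorize(y, g2))
  q1 <- sw1 * (n1 - 1) / (h1 * (h1 - 1))
  q2 <- sw2 * (n2 - 1) / (h2 * (h2 - 1))
  se <- sqrt(q1 + q2)

  if (se == 0) {
    tstat <- 0
    df <- h1 + h2 - 2
    p <- 1
  } else {
    tstat <- (tm1 - tm2) / se
    df <- (q1 + q2)^2 / (q1^2 / (h1 - 1) + q2^2 / (h2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }

  # explanatory effect size
  yhat <- c(rep(tm1, n1), rep(tm2, n2))
  sw_all <- stats::var(winsorize(c(x, y), floor(trim * (n1 + n2))))
  tot <- sw_all / winvar_const(trim)
  xi <- if (tot > 0) sqrt(min(stats::var(yhat) / tot, 1)) else 0
  d <- sign(tm1 - tm2) * xi

  crit <- stats::qt(1 - alpha / 2, df)
  structure(list(statistic = tstat, df = df, p.value = p,
                 effect_size = d, trim = trim,
                 trimmed_means = c(x = tm1, y = tm2),
                 conf.int = c(tm1 - tm2 - crit * se,
                              tm1 - tm2 + crit * se)),
            class = "yuen_test")
}

#' @export
print.yuen_test <- function(x, ...) {
  cat(sprintf("Yuen's test (%.0f%% trimmed means): t = %.3f, df = %.2f, p = %.4g, d = %.3f\n",
              100 * x$trim, x$statistic, x$df, x$p.value, x$effect_size))
  invisible(x)
}

#' Harrell-Davis quantile estimator
#'
#' Weighted average of all order statistics with beta-distributed weights;
#' a smooth, efficient quantile estimator used for decile comparisons.
#'
#' @param x Numeric sample.
#' @param probs Quantile levels.
#' @return Estimated quantiles.
#' @export
harrell_davis <- function(x, probs = seq(0.1, 0.9, by = 0.1)) {
  xs <- sort(x)
  n <- length(xs)
  vapply(probs, function(q) {
    a <- (n + 1) * q
    b <- (n + 1) * (1 - q)
    w <- stats::pbeta(seq_len(n) / n, a, b) -
      stats::pbeta((seq_len(n) - 1) / n, a, b)
    sum(w * xs)
  }, numeric(1))
}

hd_weight_matrix <- function(n, probs) {
  t(vapply(probs, function(q) {
    a <- (n + 1) * q
    b <- (n + 1) * (1 - q)
    stats::pbeta(seq_len(n) / n, a, b) -
      stats::pbeta((seq_len(n) - 1) / n, a, b)
  }, numeric(n)))
}

#' Shift function: decile-wise comparison of two distributions
#'
#' Harrell-Davis estimates of deciles 1-9 for each sample, their
#' differences `x - y`, and percentile-bootstrap confidence intervals
#' (independent resampling of each sample).
#'
#' @param x,y Numeric samples (n >= 10 each).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A data.frame of class `shift_function` with columns `decile`,
#'   `x_q`, `y_q`, `difference`, `lower`, `upper`.
#' @export
shift_function <- function(x, y, n_boot = 1000, seed = 1, conf = 0.95) {
  if (length(x) < 10 || length(y) < 10) {
    stop("shift_function: need at least 10 observations per sample")
  }
  probs <- seq(0.1, 0.9, by = 0.1)
  qx <- harrell_davis(x, probs)
  qy <- harrell_davis(y, probs)

  set.seed(seed)
  boot_hd <- function(v) {
    n <- length(v)
    W <- hd_weight_matrix(n, probs)
    B <- matrix(sample(v, n * n_boot, replace = TRUE), n, n_boot)
    W %*% apply(B, 2, sort)                     # 9 x n_boot
  }
  diffs <- boot_hd(x) - boot_hd(y)
  a <- (1 - conf) / 2
  qs <- apply(diffs, 1, stats::quantile, probs = c(a, 1 - a),
              names = FALSE)

  structure(data.frame(decile = probs, x_q = qx, y_q = qy,
                       difference = qx - qy,
                       lower = qs[1, ], upper = qs[2, ]),
            class = c("shift_function", "data.frame"))
}

#' Dichotomise traffic density from vehicle counts
#'
#' With `rule = "fixed"` a trial is dense when strictly more than
#' `threshold` vehicles are on screen (default 3). With `rule = "kde"` the
#' threshold is the centre of a Gaussian kernel density estimate of the
#' counts (Silverman's bandwidth), taken as the half-mass point of the
#' estimated density (its smoothed median): on a bimodal low/high traffic
#' mixture this lands stably in the valley separating the two regimes,
#' where discrete sample modes do not.
#'
#' @param vehicle_counts Non-negative integer counts, one per trial.
#' @param rule `"fixed"` or `"kde"`.
#' @param threshold Fixed-rule cut (default 3).
#' @return Character vector `"low"`/`"high"`; the threshold used is
#'   attached as attribute `threshold`.
#' @export
density_split <- function(vehicle_counts, rule = c("fixed", "kde"),
                          threshold = 3) {
  rule <- match.arg(rule)
  if (!length(vehicle_counts)) stop("density_split: empty counts")
  if (any(vehicle_counts < 0)) stop("density_split: counts must be >= 0")
  if (rule == "kde") {
    if (length(unique(vehicle_counts)) == 1 || length(vehicle_counts) < 2) {
      threshold <- vehicle_counts[1]
    } else {
      d <- stats::density(vehicle_counts, bw = "nrd0")
      cdf <- cumsum(d$y)
      cdf <- cdf / cdf[length(cdf)]
      threshold <- d$x[which.min(abs(cdf - 0.5))]
    }
  }
  structure(ifelse(vehicle_counts > threshold, "high", "low"),
            threshold = threshold)
}
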