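geom <- test_geometry()

# participant-level mean maps with an optional extra density disc
disc_map <- function(seed, disc_n = 0, cx = 600, cy = 400, r = 50,
                     sigma_deg = 0.25, n_base = 60) {
  set.seed(seed)
  x <- runif(n_base, 0, 1919)
  y <- runif(n_base, 0, 1079)
  if (disc_n > 0) {
    th <- runif(disc_n, 0, 2 * pi)
    rr <- r * sqrt(runif(disc_n))
    x <- c(x, cx + rr * cos(th))
    y <- c(y, cy + rr * sin(th))
  }
  build_gaze_map(list(x = x, y = y), geom, sigma_deg = sigma_deg)
}

two_group_design <- function(n_per = 6) {
  data.frame(participant_id = sprintf("p%02d", seq_len(2 * n_per)),
             age_group = rep(c("A", "B"), each = n_per))
}

test_that("identical maps give a flat zero F map", {
  m <- disc_map(1)
  maps <- rep(list(m), 8)
  sm <- pixelwise_fit(maps, two_group_design(4), "age_group")
  expect_true(all(sm$F == 0))
})

test_that("pixel-wise F equals a per-pixel linear-model oracle", {
  maps <- c(lapply(1:6, disc_map), lapply(7:12, function(s) disc_map(s, 8)))
  design <- two_group_design()
  sm <- pixelwise_fit(maps, design, "age_group")
  set.seed(5)
  px <- cbind(sample(nrow(sm$F), 10), sample(ncol(sm$F), 10))
  for (i in 1:10) {
    v <- vapply(maps, function(m) m[px[i, 1], px[i, 2]], numeric(1))
    a <- anova(stats::lm(v ~ design$age_group))
    expect_equal(sm$F[px[i, 1], px[i, 2]], a$`F value`[1], tolerance = 1e-8)
  }

  # additive two-factor model, tested effect fitted last in the oracle
  design2 <- data.frame(participant_id = design$participant_id,
                        age_group = design$age_group,
                        pedestrian_present = rep(c(0, 1), 6))
  sm2 <- pixelwise_fit(maps, design2, "age_group")
  for (i in 1:5) {
    v <- vapply(maps, function(m) m[px[i, 1], px[i, 2]], numeric(1))
    a <- anova(stats::lm(v ~ factor(design2$pedestrian_present) +
                           design2$age_group))
    expect_equal(sm2$F[px[i, 1], px[i, 2]], a$`F value`[2], tolerance = 1e-8)
  }
})

test_that("F maps are invariant to reordering of trials and detect rank deficiency", {
  maps <- c(lapply(1:6, disc_map), lapply(7:12, function(s) disc_map(s, 8)))
  design <- two_group_design()
  sm <- pixelwise_fit(maps, design, "age_group")
  perm <- sample(length(maps))
  sm_p <- pixelwise_fit(maps[perm], design[perm, ], "age_group")
  expect_equal(sm$F, sm_p$F, tolerance = 1e-10)

  design$copy <- design$age_group           # aliased factor
  expect_error(pixelwise_fit(maps, design, "age_group"), "aliased")
})

test_that("a planted gaze hotspot is localised at the right place", {
  maps <- c(lapply(1:8, disc_map),
            lapply(9:16, function(s) disc_map(s, 12, r = 50)))
  design <- two_group_design(8)
  sm <- pixelwise_fit(maps, design, "age_group")
  peak <- which(sm$F == max(sm$F), arr.ind = TRUE)
  d_px <- sqrt((peak[1, 2] * 4 - 600)^2 + (peak[1, 1] * 4 - 400)^2)
  expect_lt(d_px, 100)                       # max F inside/near the disc

  smc <- cluster_bootstrap_correct(sm, maps, design, alpha = 0.05,
                                   n_boot = 200, seed = 3)
  expect_true(all(smc$mask <= (sm$F > smc$cluster_thresh)))  # mask subset
})

test_that("a sharp additive disc effect is recovered at close to its true area", {
  # 50 x 50 px disc (1963 px): the group effect is added directly to the
  # z-scored maps (then re-z-scored), planting a known-extent difference
  grid_x <- (col(matrix(0, 270, 480)) - 0.5) * 4
  grid_y <- (row(matrix(0, 270, 480)) - 0.5) * 4
  disc <- (grid_x - 600)^2 + (grid_y - 400)^2 <= 25^2
  plant <- function(m) {
    m2 <- unclass(m) + 2 * disc
    m2 <- (m2 - mean(m2)) / sd(m2)
    attributes(m2) <- attributes(m)
    m2
  }
  maps <- c(lapply(1:8, disc_map), lapply(9:16, function(s) plant(disc_map(s))))
  design <- two_group_design(8)
  sm <- pixelwise_fit(maps, design, "age_group")
  smc <- cluster_bootstrap_correct(sm, maps, design, alpha = 0.05,
                                   n_boot = 200, seed = 3)
  area <- significant_area(smc)
  expect_gt(area, 1963 / 2)
  expect_lt(area, 1963 * 2)
})

test_that("significant area rescales grid cells to screen pixels", {
  maps <- c(lapply(1:4, disc_map), lapply(5:8, function(s) disc_map(s, 8)))
  sm <- pixelwise_fit(maps, two_group_design(4), "age_group")
  sm$mask <- matrix(TRUE, nrow(sm$F), ncol(sm$F))
  expect_equal(significant_area(sm), 1920 * 1080)
  sm$mask[] <- FALSE
  expect_equal(significant_area(sm), 0)
  expect_error(significant_area(pixelwise_fit(maps, two_group_design(4),
                                              "age_group")),
               "cluster correction")
})

test_that("group contrasts are signed, antisymmetric and zero against self", {
  maps <- c(lapply(1:4, function(s) disc_map(s, 10, cx = 500, cy = 400)),
            lapply(5:8, function(s) disc_map(s, 10, cx = 1300, cy = 650)))
  design <- two_group_design(4)

  self <- contrast_map(maps, design, "A", "A", n_boot = 100, seed = 1)
  expect_true(all(abs(self$t) < 1e-5))

  ab <- contrast_map(maps, design, "A", "B", n_boot = 100, seed = 2)
  ba <- contrast_map(maps, design, "B", "A", n_boot = 100, seed = 2)
  expect_equal(ab$t, -ba$t, tolerance = 1e-8)

  # positive t at A's hotspot, negative at B's
  expect_gt(ab$t[100, 125], 0)               # (500, 400) / 4
  expect_lt(ab$t[162, 325], 0)               # (1300, 650) / 4
  expect_error(contrast_map(maps, design, "A", "Z"), "unknown group")
})

test_that("cluster correction validates its bootstrap resolution", {
  maps <- c(lapply(1:4, disc_map), lapply(5:8, function(s) disc_map(s, 8)))
  design <- two_group_design(4)
  sm <- pixelwise_fit(maps, design, "age_group")
  expect_error(cluster_bootstrap_correct(sm, maps, design, n_boot = 50),
               "n_boot")
})
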