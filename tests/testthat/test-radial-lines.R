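# Centre localisation, surface sampling, Bresenham traversal, line metrics,
# aggregation and angular trends.

test_that("core centre is the intensity-weighted centre of mass", {
  d <- c(21, 21, 21)
  sp <- c(1, 1, 1)
  ball <- radial_field(d, sp, c(10, 10, 10)) <= 6
  inten <- array(0, d)
  inten[ball] <- 5
  none <- binary_mask(array(FALSE, d), sp)
  ctr <- find_core_center(inten, binary_mask(ball, sp), none)
  expect_equal(as.numeric(ctr), c(10, 10, 10), tolerance = 1e-9)

  # two voxels with weights 1 and 3: centre at the 1/4 : 3/4 split
  m2 <- array(FALSE, d)
  m2[5, 10, 10] <- TRUE
  m2[9, 10, 10] <- TRUE
  i2 <- array(0, d)
  i2[5, 10, 10] <- 1
  i2[9, 10, 10] <- 3
  ctr2 <- find_core_center(i2, binary_mask(m2, sp), none)
  expect_equal(as.numeric(ctr2[1]), 4 + 0.75 * 4)

  # empty difference mask: fall back with warning
  full <- binary_mask(ball, sp)
  expect_warning(cf <- find_core_center(inten, full, full), "centroid")
  expect_equal(as.numeric(cf), c(10, 10, 10), tolerance = 1e-9)
})

test_that("phantom off-centre core is recovered within one voxel", {
  sp <- phantom_spec(core_radius = 9, shell_thickness = 7, spacing = 0.9,
                     grid_shape = c(51, 51, 51),
                     center = c(25.2, 20.7, 23.4),  # off the grid centre
                     n_core_nuclei = 5, n_shell_nuclei = 12,
                     nucleus_radius_mean = 2.2, nucleus_radius_sd = 0.15,
                     rng_seed = 21)
  ph <- render_image_phantom(sp)
  geom <- render_geometry_phantom(sp)
  dapi <- adaptive_threshold(ph$stack$nuclear, sp$spacing)
  ctr <- find_core_center(ph$stack$nuclear, dapi,
                          binary_mask(geom$shell$data, sp$spacing))
  # nuclei are placed symmetrically on average; demand ~2 voxels here
  # because only ~8 core nuclei carry the weighting
  expect_lt(sqrt(sum((ctr - sp$center)^2)), 4 * 0.9)
})

test_that("concentric layers partition and ratio correctly", {
  w <- ball_mask(9, spacing = 1)
  ctr <- (dim(w$data) - 1) / 2
  all_pos <- binary_mask(array(TRUE, dim(w$data)), 1)
  lp <- concentric_layer_ratios(w, all_pos, ctr, 5)
  expect_true(all(lp$ratio == 1))
  expect_equal(sum(lp$n_voxels), sum(w$data))
  expect_equal(lp$layer, 0:1)

  # single-layer-wide mask: one layer holds every voxel
  lp2 <- concentric_layer_ratios(w, all_pos, ctr, 50)
  expect_equal(nrow(lp2), 1)
  expect_equal(lp2$n_voxels, sum(w$data))

  expect_error(concentric_layer_ratios(w, all_pos, ctr, 0), "layer_width")
  outside <- c(0, 0, 0)
  expect_error(concentric_layer_ratios(w, all_pos, outside, 5), "center")
})

test_that("geometry phantom layers show the core-shell transition", {
  spx <- phantom_spec(core_radius = 12, shell_thickness = 9, spacing = 0.9,
                      shell_label_purity = 0.7, rng_seed = 2)
  ph <- render_image_phantom(spx)
  geom <- render_geometry_phantom(spx)
  lbl <- binary_mask(ph$truth$shell_label, spx$spacing)
  lp <- concentric_layer_ratios(geom$whole, lbl, spx$center, 5)
  expect_lt(lp$ratio[1], 0.02)             # 0-5 um: core, no label
  expect_lt(lp$ratio[2], 0.02)             # 5-10 um
  shell_layers <- lp$layer >= 3 & lp$r_outer <= 21
  expect_true(all(abs(lp$ratio[shell_layers] - 0.7) < 0.05))
})

test_that("fibonacci directions are unit, antipodal at n = 2, and uniform", {
  expect_equal(fibonacci_directions(1), matrix(c(0, 0, 1), 1, 3))
  d2 <- fibonacci_directions(2)
  expect_equal(d2[1, ] + d2[2, ], c(0, 0, 0), tolerance = 1e-12)

  dirs <- fibonacci_directions(5000)
  expect_equal(rowSums(dirs^2), rep(1, 5000), tolerance = 1e-12)
  # nearest-neighbour angular spacing varies by < 2x
  nn <- numeric(5000)
  for (block in split(seq_len(5000), ceiling(seq_len(5000) / 500))) {
    cosmat <- dirs[block, , drop = FALSE] %*% t(dirs)
    cosmat[cbind(seq_along(block), block)] <- -2
    nn[block] <- acos(pmin(1, apply(cosmat, 1, max)))
  }
  expect_lt(max(nn) / min(nn), 2)
})

test_that("surface sampling recovers a ball radius to half a voxel", {
  R <- 12
  m <- ball_mask(R, spacing = 0.9)
  ctr <- (dim(m$data) - 1) / 2 * 0.9
  sp <- sample_surface_points(m, ctr, 2000)
  # exact ray-sphere oracle: per-ray within the voxel half-diagonal band,
  # the mean within half a voxel
  expect_true(all(abs(sp$r - R) <= 2 * 0.9))
  expect_lt(abs(mean(sp$r) - R), 0.45)
  expect_error(sample_surface_points(m, c(0, 0, 0), 100), "center")
})

test_that("bresenham lines satisfy the digital-line contract", {
  expect_identical(bresenham_3d(c(1, 1, 1), c(4, 1, 1)),
                   cbind(1:4, rep(1L, 4), rep(1L, 4)))
  expect_identical(bresenham_3d(c(1, 1, 1), c(3, 3, 3)),
                   cbind(1:3, 1:3, 1:3))
  set.seed(99)
  for (i in 1:1000) {
    a <- sample.int(32, 3, replace = TRUE)
    b <- sample.int(32, 3, replace = TRUE)
    p <- bresenham_3d(a, b)
    expect_identical(p[1, ], as.integer(a))
    expect_identical(p[nrow(p), ], as.integer(b))
    expect_equal(nrow(p), max(abs(b - a)) + 1)
    dif <- diff(p)
    expect_true(all(abs(dif) <= 1))             # 26-adjacency
    expect_true(all(rowSums(abs(dif)) >= 1))
    for (ax in 1:3) {                            # per-axis monotone
      expect_true(all(dif[, ax] >= 0) || all(dif[, ax] <= 0))
    }
  }
})

test_that("line metrics count positives and leading negatives", {
  d <- c(12, 3, 3)
  m <- array(FALSE, d)
  m[8:10, 2, 2] <- TRUE   # pattern NNNNNNNPPP then N
  fm <- binary_mask(m, 1)
  path <- cbind(1:10, rep(2L, 10), rep(2L, 10))
  lm <- line_metrics(path, fm, r = 10)
  expect_equal(lm$step, 1)
  expect_equal(lm$shell_thickness, 3)
  expect_equal(lm$core_radius, 7)
  expect_true(lm$covered)
  expect_equal(lm$first_positive, 8L)

  none <- line_metrics(path, binary_mask(array(FALSE, d), 1), r = 10)
  expect_equal(none$shell_thickness, 0)
  expect_false(none$covered)
  expect_true(is.na(none$core_radius))

  expect_error(line_metrics(path[0, , drop = FALSE], fm, 1), "empty")
})

test_that("aggregation computes coverage and conditional means", {
  df <- data.frame(
    theta = 0, phi = 0, r = 10, n_voxels = 10L, step = 1,
    shell_thickness = c(2, 3, 0, 5),
    core_radius = c(5, 6, NA, 7),
    covered = c(TRUE, TRUE, FALSE, TRUE),
    first_positive = c(6L, 7L, NA, 8L)
  )
  s <- aggregate_lines(df)
  expect_equal(s$coverage_percent, 75)
  expect_equal(s$mean_shell_thickness, 2.5)
  expect_equal(s$mean_shell_thickness_covered, 10 / 3)
  expect_equal(s$mean_core_radius, 6)

  df2 <- df[rep(1, 5000), ]
  df2$covered <- rep(c(TRUE, FALSE), c(4562, 438))
  expect_equal(aggregate_lines(df2)$coverage_percent, 91.24)
  df3 <- df
  df3$covered[] <- FALSE
  df3$shell_thickness[] <- 0
  s3 <- aggregate_lines(df3)
  expect_equal(s3$coverage_percent, 0)
  expect_equal(s3$mean_shell_thickness, 0)
  expect_true(is.na(s3$mean_core_radius))
})

test_that("spherical mapping round-trips to 1e-6 radians", {
  set.seed(3)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ang <- direction_to_angles(u)
  back <- angles_to_direction(ang$theta, ang$phi)
  expect_equal(back, u, tolerance = 1e-9)
  ang2 <- direction_to_angles(back)
  expect_equal(ang2$theta, ang$theta, tolerance = 1e-6)
  expect_equal(ang2$phi, ang$phi, tolerance = 1e-6)
})

test_that("line thickness matches the analytic shell chord", {
  spx <- phantom_spec(core_radius = 12, shell_thickness = 8, spacing = 0.9,
                      coverage_fraction = 0.88)
  geom <- render_geometry_phantom(spx)
  rl <- radial_line_analysis(geom$whole, geom$shell, spx$center, 2000)
  alpha <- cap_half_angle(0.88)
  dirs <- angles_to_direction(rl$lines$theta, rl$lines$phi)
  for (i in seq(1, 2000, by = 7)) {
    # skip directions within a two-voxel angular band of the cap edge,
    # where the voxelized cap boundary is genuinely ambiguous
    ang_to_cap <- acos(sum(dirs[i, ] * c(0, 0, -1)))
    if (abs(ang_to_cap - alpha) < 2 * 0.9 / 12) next
    chord <- oracle_shell_chord(dirs[i, ], 12, 20, c(0, 0, -1), alpha)
    expect_lt(abs(rl$lines$shell_thickness[i] - chord), 2 * 0.9)
  }
  covered_true <- apply(dirs, 1, function(u) {
    sum(u * c(0, 0, -1)) < cos(alpha)
  })
  # mean thickness over truly covered directions within half a voxel
  expect_equal(mean(rl$lines$shell_thickness[covered_true]), 8,
               tolerance = 0.45 / 8)
  # coverage within 1% of construction
  expect_equal(aggregate_lines(rl)$coverage_percent, 88, tolerance = 1)
})

test_that("line paths stay inside the whole mask", {
  m <- ball_mask(10, spacing = 1)
  ctr <- (dim(m$data) - 1) / 2
  rl <- radial_line_analysis(m, binary_mask(array(FALSE, dim(m$data)), 1),
                             ctr, 500)
  d <- dim(m$data)
  for (i in seq(1, 500, by = 11)) {
    p <- rl$paths[[i]]
    lin <- p[, 1] + d[1] * (p[, 2] - 1) + d[1] * d[2] * (p[, 3] - 1)
    inm <- m$data[lin]
    expect_true(all(inm[-length(inm)]))
  }
})

test_that("angular trends are flat for uniform shells and flag gaps", {
  spx <- phantom_spec(core_radius = 12, shell_thickness = 8, spacing = 0.9)
  geom <- render_geometry_phantom(spx)
  rl <- radial_line_analysis(geom$whole, geom$shell, spx$center, 3000)
  tr <- angular_trend(rl, "azimuth")
  expect_equal(nrow(tr), 20)
  expect_true(all(abs(tr$mean_thickness - 8) < 1))
  trp <- angular_trend(rl, "polar")
  expect_equal(nrow(trp), 20)
  expect_true(all(trp$n > 0))

  # single line: one populated bin, sd flagged NA
  one <- rl$lines[1, ]
  t1 <- angular_trend(one, "azimuth")
  expect_equal(sum(t1$n), 1)
  expect_true(all(is.na(t1$sd_thickness)))
  expect_error(angular_trend(one, "azimuth", bin_width = 1), "divide")
})
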