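# Watershed seeding, flooding, refinement and median nucleus volume.

test_that("seed generation finds one seed per convex object", {
  m <- ball_mask(6, spacing = 1)
  s <- make_seeds(m, h = 1)
  expect_equal(n_labels(s), 1)
  # the seed sits in the central high-distance region
  idx <- which(s$labels > 0)
  co <- arrayInd(idx, dim(m$data))
  ctr <- (dim(m$data) + 1) / 2
  expect_true(all(sqrt(rowSums(sweep(co, 2, ctr)^2)) <= 3))

  # empty mask: zero seeds
  e <- make_seeds(binary_mask(array(FALSE, c(5, 5, 5)), 1), h = 1)
  expect_equal(n_labels(e), 0)

  # h above the maximum inscribed radius suppresses everything
  s2 <- make_seeds(m, h = 10)
  expect_equal(n_labels(s2), 0)
})

test_that("dumbbell yields two seeds and a midplane watershed split", {
  db <- dumbbell_array(R = 6, offset = 4.5)
  m <- binary_mask(db$mask, 1)
  s <- make_seeds(m, h = 1)
  expect_equal(n_labels(s), 2)

  # exhaustive scan: the H-suppressed surface has exactly two maxima
  # plateaus strictly inside the two lobes
  idx <- which(s$labels > 0)
  co <- arrayInd(idx, dim(m$data))
  expect_true(all(abs(co[, 1] - db$center_plane) > 2))

  lab <- seeded_watershed(m, s)
  expect_equal(n_labels(lab), 2)
  # voxel conservation
  expect_equal(sum(lab$labels > 0), sum(m$data))
  # split plane within one voxel of the geometric neck (x = centre)
  l1 <- lab$labels == 1
  l2 <- lab$labels == 2
  co1 <- arrayInd(which(l1), dim(m$data))
  co2 <- arrayInd(which(l2), dim(m$data))
  expect_lte(abs(max(co1[, 1]) - db$center_plane), 1 + 1)
  expect_lte(abs(min(co2[, 1]) - db$center_plane), 1 + 1)
})

test_that("watershed agrees with the geodesic nearest-seed oracle", {
  skip_if_not_installed("igraph")
  db <- dumbbell_array(R = 5, offset = 3.5)
  m <- binary_mask(db$mask, 1)
  s <- make_seeds(m, h = 0.5)
  expect_equal(n_labels(s), 2)
  lab <- seeded_watershed(m, s)
  # oracle: assign each voxel to the geodesically nearest seed centroid
  d <- dim(m$data)
  seed_vox <- tapply(which(s$labels > 0), s$labels[s$labels > 0],
                     function(ix) ix[ceiling(length(ix) / 2)])
  oracle <- oracle_geodesic_labels(m$data, as.integer(seed_vox),
                                   as.integer(names(seed_vox)), c(1, 1, 1))
  # agreement away from the tie plane: allow a one-voxel boundary band
  co <- arrayInd(which(m$data), d)
  interior <- abs(co[, 1] - db$center_plane) > 1
  vox <- which(m$data)[interior]
  agree <- mean(lab$labels[vox] == oracle[vox])
  expect_gte(agree, 0.99)
})

test_that("degenerate seedings behave as contracts state", {
  m <- ball_mask(4, spacing = 1)
  # one seed -> one label covering the mask
  s <- array(0L, dim(m$data))
  s[which(m$data)[1]] <- 1L
  lab <- seeded_watershed(m, s)
  expect_equal(n_labels(lab), 1)
  expect_equal(sum(lab$labels > 0), sum(m$data))
  # every voxel its own seed -> labels equal seeds
  s2 <- array(0L, dim(m$data))
  s2[m$data] <- seq_len(sum(m$data))
  lab2 <- seeded_watershed(m, s2)
  expect_identical(lab2$labels[m$data], s2[m$data])
  # no seeds -> instructive error
  expect_error(seeded_watershed(m, array(0L, dim(m$data))), "h")
})

test_that("refinement drops undersized seeds and conserves voxels", {
  # three overlapping balls in a row: two large, one small appendage
  sp <- c(1, 1, 1)
  d <- c(46, 24, 24)
  r1 <- radial_field(d, sp, c(10, 11, 11)) <= 6
  r2 <- radial_field(d, sp, c(22, 11, 11)) <= 6
  r3 <- radial_field(d, sp, c(31, 11, 11)) <= 2.8
  m <- binary_mask(r1 | r2 | r3, sp)
  s <- make_seeds(m, h = 0.5)
  expect_gte(n_labels(s), 3)
  lab <- seeded_watershed(m, s)
  ref <- refine_watershed(lab, m, fraction = 0.7)
  # monotone: never more labels than before
  expect_lte(n_labels(ref), n_labels(lab))
  # voxel conservation after re-flooding
  expect_equal(sum(ref$labels > 0), sum(m$data))
  # the small appendage's seed is gone: volumes all >= 70% of the median
  vols <- ref$volumes
  expect_true(all(vols >= 0.7 * median(lab$volumes) | vols == max(vols)))

  # all labels equal volume: unchanged
  same <- refine_watershed(ref, m, fraction = 0.7)
  expect_identical(same$labels, ref$labels)

  # single label: unchanged by definition
  one <- seeded_watershed(m, {
    s1 <- array(0L, dim(m$data)); s1[which(m$data)[1]] <- 1L; s1
  })
  expect_identical(refine_watershed(one, m)$labels, one$labels)
})

test_that("explicit threshold arithmetic matches the refinement rule", {
  # 10 labels of ~500 um^3 and one of ~100 um^3: median 500, cut 350
  sp <- c(1, 1, 1)
  d <- c(70, 40, 30)
  centers <- rbind(
    expand.grid(x = c(8, 22, 36, 50, 64), y = c(10, 28), z = 10),
    data.frame(x = 41, y = 14, z = 10)  # overlaps the ball at (36, 10, 10)
  )
  rads <- c(rep(4.92, 10), 2.88)  # ~499 and ~100 um^3
  mask <- array(FALSE, d)
  seeds <- array(0L, d)
  for (i in seq_len(11)) {
    ball <- radial_field(d, sp, as.numeric(centers[i, ])) <= rads[i]
    mask <- mask | ball
    seeds[centers[i, 1] + 1, centers[i, 2] + 1, centers[i, 3] + 1] <-
      as.integer(i)
  }
  m <- binary_mask(mask, sp)
  lab <- seeded_watershed(m, seeds)
  expect_equal(n_labels(lab), 11)
  med <- median(lab$volumes)
  expect_true(lab$volumes[11] < 0.7 * med)
  ref <- suppressWarnings(refine_watershed(lab, m, 0.7))
  expect_equal(n_labels(ref), 10)
  expect_equal(sum(ref$labels > 0), sum(m$data))
})

test_that("median nucleus volume is the median of label volumes", {
  # construct labels as boxes of 100/200/300 voxels at unit spacing
  lab <- array(0L, c(30, 10, 10))
  lab[1:4, 1:5, 1:5] <- 1L      # 100
  lab[11:18, 1:5, 1:5] <- 2L    # 200
  lab[21:30, 1:6, 1:5] <- 3L    # 300
  lv <- label_volume(lab, c(1, 1, 1))
  expect_equal(median_nucleus_volume(lv), 200)
  one <- label_volume(array(rep(c(0L, 1L), c(3, 523)), c(526, 1, 1)),
                      c(1, 1, 1))
  expect_equal(median_nucleus_volume(one), 523)
  expect_error(median_nucleus_volume(label_volume(array(0L, c(3, 3, 3)),
                                                  1)), "empty")
})

test_that("phantom nuclei are recovered with the documented h range", {
  sp <- phantom_spec(core_radius = 11, shell_thickness = 8, spacing = 0.9,
                     n_core_nuclei = 5, n_shell_nuclei = 12,
                     nucleus_radius_mean = 2.4, nucleus_radius_sd = 0.12,
                     rng_seed = 8)
  ph <- render_image_phantom(sp)
  dapi <- adaptive_threshold(ph$stack$nuclear, sp$spacing)
  dapi <- morphological_cleanup(dapi, 0.5 * 4 / 3 * pi * 2.4^3)
  for (h in c(0.5, 1, 1.5)) {
    s <- make_seeds(dapi, h)
    lab <- refine_watershed(seeded_watershed(dapi, s), dapi)
    expect_equal(n_labels(lab), 17)
  }
  lab <- refine_watershed(seeded_watershed(dapi, make_seeds(dapi, 1)), dapi)
  mv <- median_nucleus_volume(lab)
  expect_equal(mv, median(ph$truth$nuclei$volume), tolerance = 0.1)
})
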