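test_that("local radius field matches brute-force nearest-wall search", {
  # isolated lumen pixel: nearest tissue is the adjacent pixel
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  rf <- local_radius_field(vessel_mask(m, 2.0))
  expect_equal(rf$r[5, 5], 2.0)          # 1 px at 2 um/px
  expect_true(all(rf$r[m == 0L] == 0))
  # solid disk of radius 15 px: centre radius within 1 px
  d <- matrix(0L, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 15^2) d[i, j] <- 1L
  rd <- local_radius_field(vessel_mask(d, 1))
  expect_lt(abs(rd$r[21, 21] - 15), 1 + 1e-9)
  # straight bar of width 7: centreline radius ceil(w/2) within 1 px
  b <- matrix(0L, 30, 20); b[, 7:13] <- 1L
  rb <- local_radius_field(vessel_mask(b, 1))
  expect_lt(abs(rb$r[15, 10] - ceiling(7 / 2)), 1 + 1e-9)
  # random mask against the all-pairs oracle
  blob <- random_blob(20, 18, 4)
  rr <- local_radius_field(vessel_mask(blob, 1.5))
  oracle <- sqrt(brute_dist2(blob == 0L)) * 1.5
  oracle[blob == 0L] <- 0
  expect_equal(rr$r, oracle, tolerance = 1e-12)
  # all-lumen mask has no wall
  expect_error(local_radius_field(vessel_mask(matrix(1L, 5, 5), 1)),
               "all lumen")
})

test_that("union-of-spheres occupancy equals brute-force rasterization", {
  # single pixel with r = 5 px
  m <- matrix(0, 17, 17)
  m[9, 9] <- 5
  rf <- structure(list(r = m, pixel_size = 1), class = "radius_field")
  occ <- build_occupancy(rf)
  mmax <- (dim(occ$voxels)[3] - 3) / 2
  oracle <- brute_occupancy(m, mmax)
  expect_equal(occ$voxels[, , 2:(dim(occ$voxels)[3] - 1)] == 1L, oracle)
  # voxel-ball count: strict inequality |x| < 5
  expect_equal(sum(occ$voxels),
               sum(outer(outer((-8:8)^2, (-8:8)^2, "+"), (-8:8)^2,
                         "+") < 25))
  # disk of radius R: envelope of spheres across the disk, vs oracle
  dsk <- matrix(0L, 25, 25)
  for (i in 1:25) for (j in 1:25)
    if ((i - 13)^2 + (j - 13)^2 <= 8^2) dsk[i, j] <- 1L
  rdisk <- local_radius_field(vessel_mask(dsk, 1))
  occ2 <- build_occupancy(rdisk)
  mm2 <- (dim(occ2$voxels)[3] - 3) / 2
  oracle2 <- brute_occupancy(rdisk$r, mm2)
  expect_equal(occ2$voxels[, , 2:(dim(occ2$voxels)[3] - 1)] == 1L, oracle2)
  # zero radius field -> empty occupancy
  r0 <- structure(list(r = matrix(0, 6, 6), pixel_size = 1),
                  class = "radius_field")
  expect_equal(sum(build_occupancy(r0)$voxels), 0)
  # spacing must match the pixel size
  expect_error(build_occupancy(rdisk, spacing = 2), "spacing")
})

test_that("occupancy invariants: mid-plane, monotonicity, thickness", {
  blob <- random_blob(30, 26, 21, density = 0.3)
  mask <- vessel_mask(blob, 1)
  rf <- local_radius_field(mask)
  occ <- build_occupancy(rf)
  zc <- occ$z_center_index
  # the z = 0 slice contains every lumen pixel
  expect_true(all(occ$voxels[, , zc][blob == 1L] == 1L))
  # dilating the mask never shrinks the occupancy
  dil <- blob
  dil[-1, ] <- pmax(dil[-1, ], blob[-30, ])
  dil[-30, ] <- pmax(dil[-30, ], blob[-1, ])
  dil[, -1] <- pmax(dil[, -1], blob[, -26])
  dil[, -26] <- pmax(dil[, -26], blob[, -1])
  dil[1, ] <- 0L; dil[30, ] <- 0L; dil[, 1] <- 0L; dil[, 26] <- 0L
  occ_d <- build_occupancy(local_radius_field(vessel_mask(dil, 1)))
  zc_d <- occ_d$z_center_index
  common <- min(zc - 1, zc_d - 1)
  for (mz in -common:common)
    expect_true(all(occ_d$voxels[, , zc_d + mz] >= occ$voxels[, , zc + mz]))
  # maximum z-thickness equals 2 max(r) within one voxel
  thick <- max(apply(occ$voxels, c(1, 2), sum))
  expect_lt(abs(thick - 2 * max(rf$r)), 2 + 1e-9)
})

test_that("level set equals the exhaustive signed distance oracle", {
  # single occupied voxel: face-adjacent phi = +spacing
  v <- array(0L, c(7, 7, 7)); v[4, 4, 4] <- 1L
  occ <- structure(list(voxels = v, spacing = rep(2, 3),
                        z_center_index = 4L), class = "occupancy_grid")
  ls <- compute_level_set(occ)
  expect_equal(ls$phi[3, 4, 4], 2)
  expect_equal(ls$phi[4, 4, 4], -2)
  # slab: linear profile each side of the interface
  vs <- array(0L, c(4, 4, 10)); vs[, , 1:4] <- 1L
  occs <- structure(list(voxels = vs, spacing = rep(1.5, 3),
                         z_center_index = 2L), class = "occupancy_grid")
  lss <- compute_level_set(occs)
  expect_equal(lss$phi[2, 2, ], 1.5 * c(-4, -3, -2, -1, 1, 2, 3, 4, 5, 6))
  # random blob: exact equality with the brute-force oracle
  set.seed(31)
  vb <- array(as.integer(stats::runif(10 * 9 * 8) < 0.25), c(10, 9, 8))
  if (sum(vb) == 0) vb[5, 5, 4] <- 1L
  occb <- structure(list(voxels = vb, spacing = rep(1, 3),
                         z_center_index = 4L), class = "occupancy_grid")
  lsb <- compute_level_set(occb)
  expect_equal(lsb$phi, brute_sdf(vb), tolerance = 1e-12)
  # sign must agree with the occupancy everywhere
  expect_true(all((lsb$phi < 0) == (vb == 1L)))
  # single-phase input is rejected
  occ1 <- structure(list(voxels = array(1L, c(3, 3, 3)),
                         spacing = rep(1, 3), z_center_index = 2L),
                    class = "occupancy_grid")
  expect_error(compute_level_set(occ1), "single-phase")
})

test_that("solid indicator ramps the level set as specified", {
  v <- array(0L, c(6, 6, 6)); v[2:4, 2:4, 2:4] <- 1L
  occ <- structure(list(voxels = v, spacing = rep(1, 3),
                        z_center_index = 3L), class = "occupancy_grid")
  ls <- compute_level_set(occ)
  hard <- solid_indicator(ls, smoothing_width = 0)
  expect_true(all(hard$chi %in% c(0, 1)))
  expect_true(all(hard$chi[ls$phi < 0] == 0))
  expect_true(all(hard$chi[ls$phi > 0] == 1))
  soft <- solid_indicator(ls, smoothing_width = 1)
  # ramp midpoint at the interface
  ls0 <- ls; ls0$phi[1, 1, 1] <- 0
  s0 <- solid_indicator(ls0, smoothing_width = 1)
  expect_equal(s0$chi[1, 1, 1], 0.5)
  # monotone in phi
  ord <- order(as.numeric(ls$phi))
  expect_true(all(diff(as.numeric(soft$chi)[ord]) >= -1e-12))
  expect_error(solid_indicator(ls, smoothing_width = -1), "smoothing")
})
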