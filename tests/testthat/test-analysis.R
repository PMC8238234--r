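test_that("dimensionless helpers follow their definitions", {
  expect_equal(womersley(1e-5, 1, 1e-6), 1e-2)
  expect_equal(womersley(2e-5, 1, 1e-6), 2 * womersley(1e-5, 1, 1e-6))
  expect_equal(womersley(1e-5, 4, 1e-6), 2 * womersley(1e-5, 1, 1e-6))
  expect_error(womersley(-1, 1, 1), "positive")
  expect_equal(peclet(1, 1, 1), 1)
  expect_equal(peclet(0, 1, 1), 0)
  expect_error(peclet(1, 0, 1), "positive")
  # oxygen diffusion time over 100 um at D = 1e-9 m^2/s: order 10 s
  L <- 100e-6; D <- 1e-9
  expect_equal(L^2 / D, 10)
})

fake_flow <- function(N, spacing, fu, fv, D_in = 10) {
  # faces carry the analytic values at face positions, so the
  # face-averaged cell velocity equals the analytic cell-center value
  # for (bi)linear fields
  st <- new_flow_state(N)
  xf <- (0:N[1]) * spacing
  yf <- (0:N[2]) * spacing
  xc <- (seq_len(N[1]) - 0.5) * spacing
  yc <- (seq_len(N[2]) - 0.5) * spacing
  for (k in seq_len(N[3])) {
    st$u[, , k] <- outer(xf, yc, fu)
    st$v[, , k] <- outer(xc, yf, fv)
  }
  structure(list(u = st$u, v = st$v, w = st$w, p = st$p,
                 grid = list(N = N, spacing = spacing, D_in = D_in),
                 h = spacing / D_in,
                 flux_in = 1),
            class = "steady_flow")
}

test_that("cylindrical decomposition: radial, rotational, norm", {
  N <- c(20L, 20L, 4L); sp <- 1
  orig <- c(10, 10)
  fr <- cylindrical_frame(orig, theta_artery = 0,
                          theta_vein = pi / 2)  # counterclockwise positive
  # purely radial field
  fl <- fake_flow(N, sp, fu = function(x, y) (x - orig[1]),
                  fv = function(x, y) (y - orig[2]))
  cy <- to_cylindrical(fl, fr)
  expect_lt(max(abs(cy$u_theta)), 1e-12)
  expect_true(all(cy$u_r[cy$r > 0] > 0))
  # solid rotation: u_r = 0, u_theta = r (counterclockwise)
  fl2 <- fake_flow(N, sp, fu = function(x, y) -(y - orig[2]),
                   fv = function(x, y) (x - orig[1]))
  cy2 <- to_cylindrical(fl2, fr)
  expect_lt(max(abs(cy2$u_r)), 1e-9)
  expect_equal(cy2$u_theta[, , 2], cy2$r, tolerance = 1e-9)
  # artery->vein orientation flips the azimuthal sign
  fr_cw <- cylindrical_frame(orig, theta_artery = pi / 2, theta_vein = 0)
  cy3 <- to_cylindrical(fl2, fr_cw)
  expect_equal(cy3$u_theta, -cy2$u_theta)
  # norm preservation on a random field
  set.seed(6)
  fl4 <- fake_flow(N, sp, fu = function(x, y) sin(x) + cos(2 * y),
                   fv = function(x, y) cos(x * y / 7))
  cy4 <- to_cylindrical(fl4, fr)
  cc <- cell_velocity(fl4)
  lhs <- cy4$u_r^2 + cy4$u_theta^2
  rhs <- cc$u^2 + cc$v^2
  keep <- array(rep(cy4$r > 0, N[3]), dim(lhs))
  expect_equal(lhs[keep], rhs[keep], tolerance = 1e-12)
})

test_that("region partition labels lumen cells by radius", {
  vox <- array(0L, c(20, 20, 3))
  vox[2:19, 2:19, 2] <- 1L
  occ <- structure(list(voxels = vox, spacing = rep(1, 3),
                        z_center_index = 2L), class = "occupancy_grid")
  fr <- cylindrical_frame(c(0.5, 0.5), 0, pi / 2)
  part <- partition_regions(occ, fr, fractions = 0.7)
  expect_equal(sum(part$n_cells), sum(vox))
  # farthest lumen voxel defines R_max
  expect_equal(part$R_max, sqrt(2) * 18)
  # S5-style three-region split
  p3 <- partition_regions(occ, fr, fractions = c(0.3, 0.7))
  expect_equal(length(p3$n_cells), 3)
  expect_equal(sum(p3$n_cells), sum(vox))
  expect_true(all(p3$n_cells > 0))
  # labels consistent with radii
  lab <- p3$labels[, , 2]
  rr <- sqrt(outer((((1:20) - 0.5) - 0.5)^2, (((1:20) - 0.5) - 0.5)^2,
                   "+"))
  inner <- lab == 1L & vox[, , 2] == 1L
  expect_true(all(rr[inner] <= 0.3 * p3$R_max + 1e-9))
  # a single farthest cell lands in the outer region
  vox2 <- array(0L, c(20, 20, 3))
  vox2[2:6, 2:6, 2] <- 1L
  vox2[19, 19, 2] <- 1L
  occ2 <- structure(list(voxels = vox2, spacing = rep(1, 3),
                         z_center_index = 2L), class = "occupancy_grid")
  p2 <- partition_regions(occ2, fr, fractions = 0.7)
  expect_equal(p2$labels[19, 19, 2], 2L)
  expect_equal(p2$n_cells[2], 1L)
  # errors
  expect_error(partition_regions(occ, fr, fractions = c(0.7, 0.3)),
               "increasing")
  occ0 <- structure(list(voxels = vox * 0L, spacing = rep(1, 3),
                         z_center_index = 2L), class = "occupancy_grid")
  expect_error(partition_regions(occ0, fr), "empty")
})

test_that("azimuthal flow rates integrate, normalize and add up", {
  vox <- array(0L, c(16, 16, 5))
  vox[2:15, 2:15, 2:4] <- 1L
  occ <- structure(list(voxels = vox, spacing = rep(2, 3),
                        z_center_index = 3L), class = "occupancy_grid")
  fr <- cylindrical_frame(c(1, 1), 0, pi / 2)
  part <- partition_regions(occ, fr, fractions = 0.7)
  h <- 2 / 10
  flow <- structure(list(grid = list(spacing = 2, D_in = 10), h = h,
                         flux_in = 3.2), class = "steady_flow")
  # uniform u_theta = c over all lumen cells
  ut <- array(0.5, dim(vox))
  rep1 <- azimuthal_flow_rate(ut, part, flow)
  expect_equal(sum(rep1$regions$Q_theta_raw), 0.5 * sum(vox) * h^3)
  expect_equal(rep1$regions$Q_theta_raw[1],
               0.5 * part$n_cells[1] * h^3)
  # per-volume mean recovers the constant
  expect_equal(rep1$regions$Q_theta_per_volume, c(0.5, 0.5))
  # flux normalization
  expect_equal(rep1$regions$Q_theta_normalized,
               rep1$regions$Q_theta_raw / 3.2)
  # additivity: split regions sum to the whole-domain integral
  whole <- partition_regions(occ, fr, fractions = 0.999999)
  set.seed(11)
  ur <- array(rnorm(length(vox)), dim(vox))
  r2 <- azimuthal_flow_rate(ur, part, flow)
  rw <- azimuthal_flow_rate(ur, whole, flow)
  expect_equal(sum(r2$regions$Q_theta_raw), sum(rw$regions$Q_theta_raw))
  # antisymmetric u_theta about the bisector cancels on a symmetric
  # lumen: mirror the labels' geometry through y = x
  utA <- array(0, dim(vox))
  for (k in 1:5) utA[, , k] <- outer(1:16, 1:16, function(i, j)
    (i - j) / 10)
  rA <- azimuthal_flow_rate(utA, whole, flow)
  expect_equal(rA$Q_total, 0, tolerance = 1e-12)
})

test_that("origin perturbation moves at most a shell of cells", {
  fxw <- NULL
  vox <- array(0L, c(30, 30, 3))
  set.seed(13)
  vox[, , 2] <- random_blob(30, 30, 13, density = 0.35)
  occ <- structure(list(voxels = vox, spacing = rep(1, 3),
                        z_center_index = 2L), class = "occupancy_grid")
  fr0 <- cylindrical_frame(c(2, 15), 0, pi / 2)
  fr1 <- cylindrical_frame(c(3, 15), 0, pi / 2)  # one voxel shift
  p0 <- partition_regions(occ, fr0, 0.7)
  p1 <- partition_regions(occ, fr1, 0.7)
  # bound: lumen cells within ~2 spacings of either breakpoint circle
  g <- expand.grid(x = (1:30) - 0.5, y = (1:30) - 0.5)
  lum <- vox[, , 2] == 1L
  shell <- 0L
  for (fr in list(fr0, fr1)) {
    r <- sqrt((g$x - fr$origin[1])^2 + (g$y - fr$origin[2])^2)
    near <- abs(matrix(r, 30, 30) - 0.7 * p0$R_max) <= 2.5
    shell <- shell + sum(near & lum)
  }
  expect_lte(abs(p0$n_cells[2] - p1$n_cells[2]), shell)
})

test_that("suggest_origin finds the first branch point near the inlet", {
  y <- generate_canonical("y_bifurcation",
                          params = list(domain = c(120, 100), width = 10,
                                        pixel_size = 1, angle = 25))
  o <- suggest_origin(y, inlet_face = "xlo")
  # the split sits at 0.35 Lx; the suggestion must be near it
  expect_lt(abs(o[1] - 0.35 * 120), 12)
  expect_lt(abs(o[2] - 50), 10)
})
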