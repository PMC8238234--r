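test_that("make_grid wraps occupancies and derives N = L / dx", {
  blob <- random_blob(24, 20, 2)
  occ <- build_occupancy(local_radius_field(vessel_mask(blob, 1.51)))
  g <- make_grid(occ, D_in = 12)
  expect_equal(g$N, dim(occ$voxels))
  expect_equal(g$L, dim(occ$voxels) * 1.51)
  expect_error(make_grid(occ, spacing = 2), "spacing")
  g2 <- make_grid(c(151, 75.5, 15.1), spacing = 1.51)
  expect_equal(g2$N, c(100L, 50L, 10L))
})

test_that("boundary conditions balance flux exactly", {
  # open fluid strip on xlo 3 cells, xhi 6 cells: U_out = 1/2
  chi <- array(1, c(8, 8, 4))
  chi[, 3:5, 2] <- 0          # inlet-side strip (3 faces on xlo)
  chi[8, 2:7, 1:2] <- 0       # widen near outlet
  chi[1, , ] <- 1; chi[1, 3:5, 2] <- 0
  cfg <- flow_config(inlet = boundary_patch("xlo"),
                     outlet = boundary_patch("xhi"))
  bv <- boundary_values(chi, cfg)
  expect_equal(bv$n_in, 3)
  expect_equal(bv$n_out, 12)
  expect_equal(bv$U_out, 3 / 12)
  # flux sums cancel to round-off
  flux_in <- sum(bv$ubc_lo)
  flux_out <- sum(bv$ubc_hi)
  expect_equal(flux_in - flux_out, 0)
  # equal areas give U_out = U_in
  chi2 <- array(1, c(6, 6, 3)); chi2[, 3:4, 2] <- 0
  bv2 <- boundary_values(chi2, cfg)
  expect_equal(bv2$U_out, 1)
  # state arrays receive the Dirichlet faces
  st <- new_flow_state(c(6L, 6L, 3L))
  st <- apply_boundary_conditions(st, chi2, cfg)
  expect_equal(st$u[1, 3, 2], 1)
  expect_equal(st$u[7, 3, 2], 1)
  expect_equal(sum(st$u[1, , ]) - sum(st$u[7, , ]), 0)
  # zero-overlap patches are rejected
  solid <- array(1, c(5, 5, 3))
  expect_error(boundary_values(solid, cfg), "no lumen overlap")
})

test_that("convective tendency: uniform, shear and energy identities", {
  N <- c(16L, 14L, 12L); h <- 0.1
  # uniform velocity: zero tendency in the interior
  st <- af_state_from_fun(N, h, fu = function(x, y, z) 0.7 + 0 * x,
                          fv = function(x, y, z) 0.3 + 0 * x,
                          fw = function(x, y, z) -0.2 + 0 * x)
  tend <- convective_tendency(st, h)
  expect_equal(max(abs(tend$u[4:13, 4:11, 4:9])), 0)
  expect_equal(max(abs(tend$v[4:13, 4:11, 4:9])), 0)
  # divergence-free shear u = U, v = b x: dv tendency = -U b exactly
  U <- 0.8; b <- 1.7
  st2 <- af_state_from_fun(N, h, fu = function(x, y, z) U + 0 * x,
                           fv = function(x, y, z) b * x,
                           fw = function(x, y, z) 0 * x)
  t2 <- convective_tendency(st2, h)
  expect_equal(max(abs(t2$v[4:13, 4:11, 4:9] + U * b)), 0,
               tolerance = 1e-12)
  # global kinetic-energy sum vanishes for a compact discretely
  # divergence-free field (streamfunction construction)
  set.seed(9)
  psi <- matrix(0, N[1] + 1, N[2] + 1)
  psi[5:12, 5:10] <- matrix(rnorm(8 * 6), 8, 6)
  st3 <- new_flow_state(N)
  for (k in 3:9) {
    st3$u[, 1:N[2], k] <- (psi[, 2:(N[2] + 1)] - psi[, 1:N[2]]) / h
    st3$v[1:N[1], , k] <- -(psi[2:(N[1] + 1), ] - psi[1:N[1], ]) / h
  }
  dv <- flow_divergence(st3, h)
  expect_lt(max(abs(dv)), 1e-11)
  t3 <- convective_tendency(st3, h)
  energy <- sum(st3$u * t3$u) + sum(st3$v * t3$v) + sum(st3$w * t3$w)
  scale <- sum(abs(st3$u * t3$u)) + sum(abs(st3$v * t3$v)) + 1e-30
  expect_lt(abs(energy) / scale, 1e-12)
})

test_that("diffusive tendency: linear fields, sine modes, order 2", {
  N <- c(20L, 16L, 12L); h <- 0.05; Re <- 0.1
  st <- af_state_from_fun(N, h, fu = function(x, y, z) 1 + 2 * x + 0 * z)
  td <- diffusive_tendency(st, h, Re)
  expect_lt(max(abs(td$u[5:15, 4:12, 4:8])), 1e-10)
  # u = sin(k x): interior tendency -k^2 u / Re within O(h^2)
  k1 <- 2 * pi / (N[1] * h)
  st2 <- af_state_from_fun(N, h, fu = function(x, y, z) sin(k1 * x) + 0 * z)
  t2 <- diffusive_tendency(st2, h, Re)
  i <- 5:15; j <- 6; kk <- 6
  expected <- -k1^2 / Re * st2$u[i, j, kk]
  expect_lt(max(abs(t2$u[i, j, kk] - expected)) /
              max(abs(expected)), (k1 * h)^2)
  # Richardson: halving h reduces the sine-mode error ~4x
  err_at <- function(nx, h) {
    NN <- c(as.integer(nx), 8L, 8L)
    kx <- 2 * pi / (nx * h)
    s <- af_state_from_fun(NN, h,
                           fu = function(x, y, z) sin(kx * x) + 0 * z)
    t <- diffusive_tendency(s, h, Re)
    ii <- seq(3, nx - 2)
    max(abs(t$u[ii, 4, 4] + kx^2 / Re * s$u[ii, 4, 4]))
  }
  L <- 1.6
  e1 <- err_at(16, L / 16)
  e2 <- err_at(32, L / 32)
  slope <- log2(e1 / e2)
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("penalization tendency is -eta * chi * u on faces", {
  N <- c(8L, 8L, 6L)
  st <- af_state_from_fun(N, 0.1, fu = function(x, y, z) 0.5 + 0 * x,
                          fv = function(x, y, z) -0.25 + 0 * x)
  chi0 <- array(0, N)
  t0 <- penalization_tendency(st, chi0, eta = 1e4)
  expect_equal(max(abs(t0$u)), 0)
  chi1 <- array(1, N)
  t1 <- penalization_tendency(st, chi1, eta = 1e3)
  expect_equal(unique(as.numeric(t1$u)), -1e3 * 0.5)
  expect_equal(unique(as.numeric(t1$v)), 1e3 * 0.25)
  # face averaging of a half-solid domain
  chih <- array(0, N); chih[5:8, , ] <- 1
  th <- penalization_tendency(st, chih, eta = 10)
  expect_equal(th$u[5, 4, 3], -10 * 0.5 * 0.5)  # face between phases
  expect_error(penalization_tendency(st, chi0, eta = 0), "eta")
})

test_that("pressure Poisson solver meets its residual contract", {
  N <- c(24L, 20L, 10L); h <- 0.2
  # zero rhs -> zero mean-pinned solution
  z <- pressure_poisson_solve(array(0, N), h)
  expect_equal(max(abs(z$x)), 0)
  # manufactured Neumann-compatible solution, discrete residual check
  xc <- (1:N[1] - 0.5) * h; yc <- (1:N[2] - 0.5) * h; zc <- (1:N[3] - 0.5) * h
  Lx <- N[1] * h; Ly <- N[2] * h; Lz <- N[3] * h
  sol <- array(0, N)
  for (k in 1:N[3])
    sol[, , k] <- outer(cos(pi * xc / Lx), cos(2 * pi * yc / Ly)) *
      cos(pi * zc[k] / Lz)
  lam <- -(pi / Lx)^2 - (2 * pi / Ly)^2 - (pi / Lz)^2
  rhs <- lam * sol
  for (method in c("mg", "cg")) {
    res <- pressure_poisson_solve(rhs, h, tol = 1e-9, method = method)
    expect_lte(res$relres, 1e-9)
    expect_lt(mean(abs(res$x)), 1)  # zero-mean pinning
    # independent residual evaluation with a Neumann 7-point stencil
    pad <- res$x
    lap <- array(0, N)
    gx <- function(i) pad[pmin(pmax(i, 1), N[1]), , , drop = FALSE]
    lap <- (pad[c(2:N[1], N[1]), , ] + pad[c(1, 1:(N[1] - 1)), , ] +
            pad[, c(2:N[2], N[2]), ] + pad[, c(1, 1:(N[2] - 1)), ] +
            pad[, , c(2:N[3], N[3])] + pad[, , c(1, 1:(N[3] - 1))] -
            6 * pad) / h^2
    rhs0 <- rhs - mean(rhs)
    expect_lt(sqrt(mean((lap - rhs0)^2)) / sqrt(mean(rhs0^2)), 1e-8)
    # O(h^2) agreement with the continuum solution
    err <- res$x - (sol - mean(sol))
    expect_lt(sqrt(mean(err^2)) / sqrt(mean(sol^2)), 0.02)
  }
})

test_that("discrete divergence matches a direct finite difference", {
  N <- c(10L, 9L, 8L); h <- 0.3
  set.seed(4)
  st <- new_flow_state(N)
  st$u[] <- rnorm(length(st$u))
  st$v[] <- rnorm(length(st$v))
  st$w[] <- rnorm(length(st$w))
  dv <- flow_divergence(st, h)
  i <- 4; j <- 5; k <- 3
  expect_equal(dv[i, j, k],
               (st$u[i + 1, j, k] - st$u[i, j, k] +
                st$v[i, j + 1, k] - st$v[i, j, k] +
                st$w[i, j, k + 1] - st$w[i, j, k]) / h)
})
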