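# Session-memoised heavy fixtures so multiple test files can share one
# solver run.

.af_cache <- new.env(parent = emptyenv())

af_fixture <- function(name, fun) {
  if (!exists(name, envir = .af_cache)) assign(name, fun(), envir = .af_cache)
  get(name, envir = .af_cache)
}

# small penalized tube (10 cells per diameter), converged
af_mini_tube <- function(eta = 1e4) {
  af_fixture(paste0("mini_tube_", eta), function() {
    g <- analytic_tube_geometry(nx = 48, n_cross = 20, diameter_cells = 10,
                                spacing = 1.51, smoothing_width = 1)
    cfg <- flow_config(eta = eta, steady_tol = 1e-6, max_steps = 3000)
    flow <- suppressWarnings(run_to_steady_state(g$chi, g$grid, cfg))
    list(g = g, flow = flow)
  })
}

# a small wedge pipeline run (mask -> reconstruction -> flow -> report)
af_wedge_run <- function(preset, dom = 240, pxs = 2, seed = 7,
                         fractions = 0.7) {
  af_fixture(paste0("wedge_", preset, "_", dom, "_", pxs), function() {
    spec <- wedge_preset(preset, domain_size = c(dom, dom),
                         pixel_size = pxs, inlet_diameter = 12,
                         capillary_diameter = 7, seed = seed)
    mask <- generate_wedge(spec)
    mo <- morphometry(mask)
    geom <- reconstruct_geometry(mask, smoothing_width = 1)
    grid <- make_grid(geom$occupancy, D_in = spec$inlet_diameter)
    pat <- wedge_boundary_patches(mask, geom$occupancy)
    cfg <- flow_config(inlet = pat$inlet, outlet = pat$outlet,
                       steady_tol = 1e-6, max_steps = 6000)
    flow <- run_to_steady_state(geom$solid$chi, grid, cfg)
    frame <- cylindrical_frame(attr(mask, "origin"),
                               attr(mask, "theta_artery"),
                               attr(mask, "theta_vein"))
    part <- partition_regions(geom$occupancy, frame, fractions = fractions)
    cyl <- to_cylindrical(flow, frame)
    rep <- azimuthal_flow_rate(cyl$u_theta, part, flow)
    list(spec = spec, mask = mask, mo = mo, geom = geom, grid = grid,
         flow = flow, frame = frame, part = part, cyl = cyl, rep = rep)
  })
}

# staggered state filled from cell-center functions (for operator tests)
af_state_from_fun <- function(N, h, fu = function(x, y, z) 0 * x,
                              fv = fu, fw = fu) {
  st <- new_flow_state(N)
  xf <- (0:N[1]) * h
  yc <- ((1:N[2]) - 0.5) * h
  zc <- ((1:N[3]) - 0.5) * h
  xc <- ((1:N[1]) - 0.5) * h
  yf <- (0:N[2]) * h
  zf <- (0:N[3]) * h
  for (k in seq_len(N[3])) for (j in seq_len(N[2]))
    st$u[, j, k] <- fu(xf, yc[j], zc[k])
  for (k in seq_len(N[3])) for (j in seq_len(N[2] + 1))
    st$v[, j, k] <- fv(xc, yf[j], zc[k])
  for (k in seq_len(N[3] + 1)) for (j in seq_len(N[2]))
    st$w[, j, k] <- fw(xc, yc[j], zf[k])
  st
}
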