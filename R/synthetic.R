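# Synthetic artery-capillary-vein wedge networks.  The geometry mimics
# the minimum flow unit of the neonatal mouse retina: a single feeding
# artery and a single draining vein radiating from near the optic nerve
# head, with the capillary plexus in between represented as concentric
# arcs (azimuthal capillaries) joined by radial connector segments.
# Branch density is tuned through the number of rings and connectors per
# ring; no biological growth process is modelled.

#' Specification of a synthetic A-V wedge network
#'
#' @param domain_size `(Lx, Ly)` in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param inlet_diameter artery diameter at the inlet (um).
#' @param capillary_diameter capillary diameter (um); must map to
#'   >= 3 px.
#' @param n_radial_rings number of concentric capillary arcs.
#' @param branches_per_ring radial connector segments per ring gap (the
#'   branch-density knob).
#' @param wedge_angle opening angle between artery and vein rays
#'   (degrees).
#' @param ring_compression exponent biasing ring placement toward the
#'   wedge apex (1 = uniform spacing; > 1 concentrates rings in the
#'   inner plexus, where hyper-branching phenotypes add vessels, while
#'   keeping the outermost ring at the front rim).
#' @param jitter fractional positional jitter of connector angles in
#'   `[0, 1]`.
#' @param seed RNG seed; the same spec yields an identical mask.
#' @return object of class `synthetic_network_spec`.
#' @export
synthetic_network_spec <- function(domain_size = c(600, 600),
                                   pixel_size = 1.51,
                                   inlet_diameter = 12.08,
                                   capillary_diameter = 7,
                                   n_radial_rings = 6,
                                   branches_per_ring = 10,
                                   wedge_angle = 60,
                                   ring_compression = 1,
                                   jitter = 0.35,
                                   seed = 1L) {
  spec <- structure(list(domain_size = domain_size,
                         pixel_size = pixel_size,
                         inlet_diameter = inlet_diameter,
                         capillary_diameter = capillary_diameter,
                         n_radial_rings = as.integer(n_radial_rings),
                         branches_per_ring = as.integer(branches_per_ring),
                         wedge_angle = wedge_angle,
                         ring_compression = ring_compression,
                         jitter = jitter,
                         seed = as.integer(seed)),
                    class = "synthetic_network_spec")
  if (capillary_diameter / pixel_size < 3)
    stop("capillary_diameter must be at least 3 pixels")
  if (inlet_diameter < capillary_diameter)
    stop("inlet_diameter must be >= capillary_diameter")
  if (wedge_angle <= 0 || wedge_angle >= 180)
    stop("wedge_angle must lie in (0, 180) degrees")
  if (jitter < 0 || jitter > 1) stop("jitter must lie in [0, 1]")
  spec
}

#' Hyper- and hypo-branching preset specifications
#'
#' Matched wedge specs differing only in branch density: same domain,
#' inlet, capillary caliber and outer radius, with the hyper variant
#' carrying more capillary rings and more connectors per ring (denser
#' plexus) than the hypo variant.
#'
#' @param preset `"hyper"` or `"hypo"`.
#' @param ... overrides passed to [synthetic_network_spec()].
#' @return a `synthetic_network_spec`.
#' @export
wedge_preset <- function(preset = c("hyper", "hypo"), ...) {
  preset <- match.arg(preset)
  base <- list(...)
  dens <- if (preset == "hyper") {
    list(n_radial_rings = 9L, branches_per_ring = 16L,
         ring_compression = 1.7)
  } else {
    list(n_radial_rings = 5L, branches_per_ring = 7L,
         ring_compression = 1)
  }
  do.call(synthetic_network_spec, utils::modifyList(dens, base))
}

# --- raster drawing helpers (pixel centers at (i - 0.5) * px) ---------

# distance from points to segment (x1,y1)-(x2,y2)
seg_dist <- function(px_x, px_y, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px_x - x1)^2 + (px_y - y1)^2))
  t <- clamp(((px_x - x1) * vx + (px_y - y1) * vy) / L2, 0, 1)
  sqrt((px_x - x1 - t * vx)^2 + (px_y - y1 - t * vy)^2)
}

draw_segment <- function(canvas, px, x1, y1, x2, y2, w1, w2 = w1) {
  d <- dim(canvas)
  pad <- max(w1, w2) / 2 + px
  i0 <- max(1L, floor(min(x1, x2) - pad) %/% px + 1L)
  i1 <- min(d[1], ceiling((max(x1, x2) + pad) / px))
  j0 <- max(1L, floor(min(y1, y2) - pad) %/% px + 1L)
  j1 <- min(d[2], ceiling((max(y1, y2) + pad) / px))
  if (i0 > i1 || j0 > j1) return(canvas)
  xs <- (i0:i1 - 0.5) * px
  ys <- (j0:j1 - 0.5) * px
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) matrix(0, nrow(X), ncol(X)) else
    clamp(((X - x1) * vx + (Y - y1) * vy) / L2, 0, 1)
  dist <- sqrt((X - x1 - t * vx)^2 + (Y - y1 - t * vy)^2)
  halfw <- (w1 + (w2 - w1) * t) / 2
  canvas[i0:i1, j0:j1] <- canvas[i0:i1, j0:j1] | (dist <= halfw)
  canvas
}

draw_disk <- function(canvas, px, cx, cy, w) {
  draw_segment(canvas, px, cx, cy, cx, cy, w)
}

draw_arc <- function(canvas, px, cx, cy, radius, th0, th1, w) {
  d <- dim(canvas)
  pad <- w / 2 + px
  i0 <- max(1L, floor(cx - radius - pad) %/% px + 1L)
  i1 <- min(d[1], ceiling((cx + radius + pad) / px))
  j0 <- max(1L, floor(cy - radius - pad) %/% px + 1L)
  j1 <- min(d[2], ceiling((cy + radius + pad) / px))
  if (i0 > i1 || j0 > j1) return(canvas)
  xs <- (i0:i1 - 0.5) * px
  ys <- (j0:j1 - 0.5) * px
  X <- matrix(xs, length(xs), length(ys)) - cx
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE) - cy
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  inside <- abs(r - radius) <= w / 2 & th >= th0 & th <= th1
  canvas[i0:i1, j0:j1] <- canvas[i0:i1, j0:j1] | inside
  canvas
}

# connected component containing any seed pixel (4/8-connectivity BFS)
mask_component <- function(px, seeds) {
  d <- dim(px)
  lab <- matrix(FALSE, d[1], d[2])
  stack <- seeds[px[seeds]]
  lab[stack] <- TRUE
  nxo <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  nyo <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  frontier <- stack
  while (length(frontier)) {
    ij <- arrayInd(frontier, d)
    nbr <- integer(0)
    for (q in 1:8) {
      ii <- ij[, 1] + nxo[q]; jj <- ij[, 2] + nyo[q]
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      cand <- (jj[ok] - 1L) * d[1] + ii[ok]
      cand <- cand[px[cand] & !lab[cand]]
      if (length(cand)) { lab[cand] <- TRUE; nbr <- c(nbr, cand) }
    }
    frontier <- unique(nbr)
  }
  lab
}

#' Generate a synthetic A-V wedge mask
#'
#' Draws an artery ray and a vein ray from a common origin just outside
#' the left domain edge (so their crossings of the edge form separated
#' inlet and outlet stubs), concentric capillary arcs between them, and
#' jittered radial connectors; every lumen pixel is connected to both
#' stubs and the mask touches the boundary only at the stubs.
#'
#' @param spec a [synthetic_network_spec()].
#' @return a [vessel_mask()]; attributes `origin` (analysis origin, um,
#'   clamped inside the domain), `theta_artery`, `theta_vein`,
#'   `inlet_span_y`, `outlet_span_y` (um ranges on the `x = 0` edge).
#' @export
generate_wedge <- function(spec) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  px <- spec$pixel_size
  Lx <- spec$domain_size[1]; Ly <- spec$domain_size[2]
  nx <- as.integer(round(Lx / px)); ny <- as.integer(round(Ly / px))
  phi <- spec$wedge_angle * pi / 180
  d_in <- spec$inlet_diameter; d_cap <- spec$capillary_diameter
  # origin left of the edge so artery/vein cross x = 0 well apart
  cset <- 2 * d_in / tan(phi / 2)
  O <- c(-cset, Ly / 2)
  th_a <- +phi / 2; th_v <- -phi / 2
  margin <- 3 + d_cap / 2
  R_outer <- min(Lx + cset - margin, (Ly / 2 - margin) / sin(phi / 2))
  if (R_outer < 4 * d_in) stop("infeasible spec: domain too small")
  r0 <- cset / cos(phi / 2)  # edge-crossing radius of both rays
  r_in <- r0 + 1.8 * d_in
  u <- (seq_len(spec$n_radial_rings) / spec$n_radial_rings)^
    spec$ring_compression
  rings <- r_in + (R_outer - r_in) * u
  if (length(rings) >= 2 && min(diff(rings)) < d_cap)
    stop("infeasible spec: rings collide (increase domain or reduce rings)")
  canvas <- matrix(FALSE, nx, ny)
  taper_end <- 1.25 * d_cap
  for (th in c(th_a, th_v)) {
    canvas <- draw_segment(canvas, px,
                           O[1], O[2],
                           O[1] + R_outer * cos(th), O[2] + R_outer * sin(th),
                           d_in, taper_end)
  }
  for (rho in rings)
    canvas <- draw_arc(canvas, px, O[1], O[2], rho, th_v, th_a, d_cap)
  # jittered radial connectors per ring gap
  oseed <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  on.exit({
    if (!is.null(oseed)) assign(".Random.seed", oseed, envir = globalenv())
  })
  gaps <- cbind(rings[-length(rings)], rings[-1])
  B <- spec$branches_per_ring
  if (nrow(gaps) > 0 && B > 0) {
    for (g in seq_len(nrow(gaps))) {
      # cap the connector count so neighbouring connectors stay separated
      # by at least ~1.3 capillary diameters along the inner arc (dense
      # presets must stay reticular, not merge into solid sheets)
      Bg <- min(B, max(2L, floor(gaps[g, 1] * phi / (1.3 * d_cap))))
      base <- th_v + (seq_len(Bg) - 0.5) * phi / Bg
      off <- spec$jitter * ((g %% 2) - 0.5) * phi / (2 * Bg)
      ang <- base + off +
        spec$jitter * stats::runif(Bg, -0.4, 0.4) * phi / Bg
      ang <- clamp(ang, th_v + 0.02, th_a - 0.02)
      for (a in ang)
        canvas <- draw_segment(canvas, px,
                               O[1] + gaps[g, 1] * cos(a),
                               O[2] + gaps[g, 1] * sin(a),
                               O[1] + gaps[g, 2] * cos(a),
                               O[2] + gaps[g, 2] * sin(a),
                               d_cap)
    }
  }
  # keep the component attached to the inlet stub; require the outlet
  ya <- O[2] + tan(th_a) * cset; yv <- O[2] + tan(th_v) * cset
  jrange <- function(y) {
    j <- as.integer(round((y + c(-1, 1) * d_in / 2) / px))
    seq(max(1L, j[1]), min(ny, j[2]))
  }
  seeds <- (jrange(ya) - 1L) * nx + 1L
  comp <- mask_component(canvas, seeds)
  if (!any(comp[1, jrange(yv)]))
    stop("generated network is not inlet-outlet connected")
  mask <- vessel_mask(matrix(as.integer(comp), nx, ny), px)
  attr(mask, "origin") <- c(max(O[1], 0.5 * px), O[2])
  attr(mask, "theta_artery") <- th_a
  attr(mask, "theta_vein") <- th_v
  # vertical chord of an oblique band of width d_in crossing x = 0
  halfspan <- (d_in / 2) / cos(phi / 2) + px
  attr(mask, "inlet_span_y") <- ya + c(-1, 1) * halfspan
  attr(mask, "outlet_span_y") <- yv + c(-1, 1) * halfspan
  attr(mask, "spec") <- spec
  mask
}

#' Boundary patches for a generated wedge mask
#'
#' Translates the inlet/outlet stub locations recorded by
#' [generate_wedge()] into [boundary_patch()]es on the `x = 0` face of
#' the reconstructed occupancy grid (both the artery and the vein cross
#' that edge).
#'
#' @param mask a mask from [generate_wedge()].
#' @param occ the `occupancy_grid` reconstructed from it.
#' @return list with `inlet` and `outlet` patches.
#' @export
wedge_boundary_patches <- function(mask, occ) {
  px <- mask$pixel_size
  N <- dim(occ$voxels)
  span_cells <- function(yr) {
    j <- c(max(1L, as.integer(floor(yr[1] / px)) + 1L),
           min(N[2], as.integer(ceiling(yr[2] / px))))
    list(j, c(1L, N[3]))
  }
  list(inlet = boundary_patch("xlo",
                              span_cells(attr(mask, "inlet_span_y"))),
       outlet = boundary_patch("xlo",
                               span_cells(attr(mask, "outlet_span_y"))))
}

#' Canonical validation geometries
#'
#' Exact parametric masks for solver validation: a straight tube (bar),
#' a mirror-symmetric Y-bifurcation, and a single loop (one hole).
#'
#' @param name `"straight_tube"`, `"y_bifurcation"` or `"single_loop"`.
#' @param params named list of overrides: `domain` (um, length 2),
#'   `width` (vessel diameter, um), `pixel_size`, `angle` (degrees,
#'   Y-branch half-angle).
#' @return a [vessel_mask()].
#' @export
generate_canonical <- function(name = c("straight_tube", "y_bifurcation",
                                        "single_loop"),
                               params = list()) {
  name <- match.arg(name)
  defaults <- switch(name,
    straight_tube = list(domain = c(200, 60), width = 12,
                         pixel_size = 1, angle = 30),
    y_bifurcation = list(domain = c(200, 160), width = 12,
                         pixel_size = 1, angle = 22),
    single_loop = list(domain = c(200, 100), width = 12,
                       pixel_size = 1, angle = 30))
  p <- utils::modifyList(defaults, params)
  px <- p$pixel_size
  nx <- as.integer(round(p$domain[1] / px))
  ny <- as.integer(round(p$domain[2] / px))
  Lx <- nx * px; Ly <- ny * px
  canvas <- matrix(FALSE, nx, ny)
  ymid <- Ly / 2
  if (name == "straight_tube") {
    half_w_px <- round(p$width / px / 2)
    jmid <- ny / 2
    rows <- max(1, floor(jmid - half_w_px + 1)):min(ny, floor(jmid + half_w_px))
    canvas[, rows] <- TRUE
  } else if (name == "y_bifurcation") {
    xsplit <- 0.35 * Lx
    th <- p$angle * pi / 180
    canvas <- draw_segment(canvas, px, 0, ymid, xsplit, ymid, p$width)
    dy <- (Lx - xsplit) * tan(th)
    canvas <- draw_segment(canvas, px, xsplit, ymid, Lx, ymid + dy, p$width)
    canvas <- draw_segment(canvas, px, xsplit, ymid, Lx, ymid - dy, p$width)
  } else {
    xa <- 0.25 * Lx; xb <- 0.75 * Lx
    dy <- 0.22 * Ly
    canvas <- draw_segment(canvas, px, 0, ymid, xa, ymid, p$width)
    canvas <- draw_segment(canvas, px, xa, ymid, 0.5 * Lx, ymid + dy, p$width)
    canvas <- draw_segment(canvas, px, 0.5 * Lx, ymid + dy, xb, ymid, p$width)
    canvas <- draw_segment(canvas, px, xa, ymid, 0.5 * Lx, ymid - dy, p$width)
    canvas <- draw_segment(canvas, px, 0.5 * Lx, ymid - dy, xb, ymid, p$width)
    canvas <- draw_segment(canvas, px, xb, ymid, Lx, ymid, p$width)
    for (pt in list(c(xa, ymid), c(xb, ymid), c(0.5 * Lx, ymid + dy),
                    c(0.5 * Lx, ymid - dy)))
      canvas <- draw_disk(canvas, px, pt[1], pt[2], 1.4 * p$width)
  }
  vessel_mask(matrix(as.integer(canvas), nx, ny), px)
}
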