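# Analytic validation geometries built directly as solid-indicator
# arrays (no image stage): a circular tube and a plane channel.  Used
# by the solver validation tests and the acceptance checks.

#' Analytic circular-tube geometry for solver validation
#'
#' A straight cylinder along x, centered in the (y, z) cross-section,
#' embedded by the signed distance to the cylinder wall with the usual
#' indicator ramp.  With Hagen-Poiseuille flow the axial profile is
#' `u(r) = 2 u_b (1 - (r/R)^2)` and `u_max / u_bulk = 2`.
#'
#' @param nx cells along the tube.
#' @param n_cross cells across each transverse axis.
#' @param diameter_cells tube diameter in cells (>= 10 for profile
#'   checks).
#' @param spacing grid spacing in micrometres.
#' @param smoothing_width indicator ramp half-width in cells.
#' @return list with `chi`, `grid` (a [make_grid()]), `R_um`,
#'   `center_um`.
#' @export
analytic_tube_geometry <- function(nx = 200, n_cross = 64,
                                   diameter_cells = 12, spacing = 1.51,
                                   smoothing_width = 1) {
  ny <- n_cross; nz <- n_cross
  D_um <- diameter_cells * spacing
  R_um <- D_um / 2
  yc <- (ny / 2) * spacing  # tube axis through a cell-face center line
  zc <- (nz / 2) * spacing
  y <- (seq_len(ny) - 0.5) * spacing
  z <- (seq_len(nz) - 0.5) * spacing
  rr <- sqrt(outer((y - yc)^2, (z - zc)^2, "+"))
  phi2d <- rr - R_um  # signed distance to the wall, tissue positive
  chi2d <- if (smoothing_width == 0) (phi2d > 0) + 0 else
    clamp(0.5 + phi2d / (2 * smoothing_width * spacing), 0, 1)
  chi <- array(rep(chi2d, each = nx), dim = c(nx, ny, nz))
  grid <- make_grid(c(nx, ny, nz) * spacing, spacing = spacing,
                    D_in = D_um)
  list(chi = chi, grid = grid, R_um = R_um, center_um = c(yc, zc))
}

#' Analytic plane-channel geometry for solver validation
#'
#' Penalized slabs bound the flow in y; the z extent is made wide so the
#' mid-plane profile approaches the planar Poiseuille parabola with
#' `u_max / u_bulk = 1.5`.
#'
#' @param nx cells along the channel.
#' @param gap_cells fluid gap in cells.
#' @param wall_cells solid slab thickness per side.
#' @param nz cells across z (aspect `nz / gap_cells` should be >= 5
#'   for a near-planar core).
#' @param spacing grid spacing in micrometres.
#' @param smoothing_width indicator ramp half-width in cells.
#' @return list with `chi`, `grid`, `gap_um`, `fluid_rows`.
#' @export
analytic_channel_geometry <- function(nx = 128, gap_cells = 12,
                                      wall_cells = 4, nz = 72,
                                      spacing = 1.51,
                                      smoothing_width = 1) {
  ny <- gap_cells + 2 * wall_cells
  H_um <- gap_cells * spacing
  ylo <- wall_cells * spacing          # wall planes
  yhi <- (wall_cells + gap_cells) * spacing
  y <- (seq_len(ny) - 0.5) * spacing
  phi <- pmax(ylo - y, y - yhi)        # signed distance to nearer wall
  chirow <- if (smoothing_width == 0) (phi > 0) + 0 else
    clamp(0.5 + phi / (2 * smoothing_width * spacing), 0, 1)
  chi <- array(rep(rep(chirow, each = nx), times = nz),
               dim = c(nx, ny, nz))
  grid <- make_grid(c(nx, ny, nz) * spacing, spacing = spacing,
                    D_in = H_um)
  list(chi = chi, grid = grid, gap_um = H_um,
       fluid_rows = (wall_cells + 1):(wall_cells + gap_cells))
}
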