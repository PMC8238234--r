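#' Local radius field of a vessel mask
#'
#' For each lumen pixel, the Euclidean distance from its center to the
#' nearest tissue pixel center: the local vessel radius used to place
#' the reconstruction spheres.  Computed with an exact squared-distance
#' transform.
#'
#' @param mask a [vessel_mask()] with at least one tissue pixel.
#' @return object of class `radius_field`: `r` (micrometres, zero on
#'   tissue) and `pixel_size`.
#' @export
local_radius_field <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  px <- mask$pixels
  if (all(px == 1L)) stop("mask is all lumen: no wall to measure against")
  f <- array(ifelse(px == 0L, 0, Inf), dim = c(dim(px), 1L))
  d2 <- .cpp_gdt(f, dim(f))
  r <- sqrt(d2[, , 1]) * mask$pixel_size
  r[px == 0L] <- 0
  structure(list(r = r, pixel_size = mask$pixel_size),
            class = "radius_field")
}

#' Union-of-spheres 3D occupancy from a radius field
#'
#' Places at every lumen pixel `p` a sphere of radius `r(p)` centered on
#' the image plane `z = 0` and marks voxel `v` as lumen iff
#' `||center(v) - (p, 0)|| < r(p)` for some `p` (strict inequality).
#' The maximum over spheres is evaluated with the parabolic-envelope
#' identity: `v = (x, y, z)` is occupied iff
#' `z^2 < max_p [ r(p)^2 - ||xy - p||^2 ]`,
#' one generalized 2D distance transform plus a per-plane test.
#'
#' The voxel grid is isotropic with spacing equal to the mask pixel size
#' (resample the mask first if a different solver spacing is wanted);
#' `z = 0` is a cell-center plane recorded in `z_center_index`, and the
#' z extent covers the thickest vessel plus one tissue voxel on each
#' side.
#'
#' @param radius a `radius_field` from [local_radius_field()].
#' @param spacing voxel spacing in micrometres; must equal the mask
#'   pixel size (isotropic grid).
#' @return object of class `occupancy_grid`: `voxels` (0/1 integer 3D
#'   array), `spacing` (length-3, micrometres) and `z_center_index`.
#' @export
build_occupancy <- function(radius, spacing = radius$pixel_size) {
  stopifnot(inherits(radius, "radius_field"))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(abs(spacing - radius$pixel_size) > 1e-9 * radius$pixel_size))
    stop("occupancy spacing must equal the mask pixel size; ",
         "use resample_mask() to change resolution first")
  if (is.null(radius$r) || length(radius$r) == 0)
    stop("empty radius field")
  r_px <- radius$r / radius$pixel_size
  d <- dim(r_px)
  if (all(r_px <= 0)) {
    # no spheres to place: empty (all-tissue) occupancy
    occ <- array(0L, dim = c(d[1], d[2], 3L))
    return(structure(list(voxels = occ, spacing = spacing,
                          z_center_index = 2L), class = "occupancy_grid"))
  }
  r_px2 <- r_px^2
  # squared radii from a pixel distance transform are exact integers;
  # snap the sqrt/square round-trip noise so the strict inequality
  # m^2 < r^2 - d^2 breaks integer ties exactly
  near <- abs(r_px2 - round(r_px2)) < 1e-6 * pmax(1, r_px2)
  r_px2[near] <- round(r_px2[near])
  f <- array(ifelse(r_px > 0, -r_px2, Inf), dim = c(d, 1L))
  env <- -.cpp_gdt(f, dim(f))[, , 1]   # max_p [ r^2 - d^2 ], px^2 units
  emax <- max(env)
  mmax <- ceiling(sqrt(emax)) - 1
  while ((mmax + 1)^2 < emax) mmax <- mmax + 1
  nz <- 2L * as.integer(mmax) + 3L  # one tissue voxel padding per side
  zc <- as.integer(mmax) + 2L
  d <- dim(r_px)
  occ <- array(0L, dim = c(d[1], d[2], nz))
  for (m in -mmax:mmax)
    occ[, , zc + m] <- occ[, , zc + m] | (m^2 < env)
  storage.mode(occ) <- "integer"
  structure(list(voxels = occ, spacing = spacing, z_center_index = zc),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "occupancy_grid: %d x %d x %d voxels at %.3g um, %d lumen (%.2f%%)\n",
    d[1], d[2], d[3], x$spacing[1], sum(x$voxels),
    100 * mean(x$voxels)))
  invisible(x)
}

#' Signed-distance (level-set) field of an occupancy grid
#'
#' Exact voxel-center-to-voxel-center Euclidean distance across the
#' lumen/tissue interface: positive in tissue (distance to the nearest
#' lumen voxel center), negative inside the lumen (distance to the
#' nearest tissue voxel center).
#'
#' @param occ an `occupancy_grid` containing both phases.
#' @return object of class `level_set`: `phi` (micrometres), `spacing`,
#'   `z_center_index`.
#' @export
compute_level_set <- function(occ) {
  stopifnot(inherits(occ, "occupancy_grid"))
  vox <- occ$voxels
  if (all(vox == 1L) || all(vox == 0L))
    stop("occupancy grid is single-phase; signed distance undefined")
  d <- dim(vox)
  f_lum <- array(ifelse(vox == 1L, 0, Inf), dim = d)
  f_tis <- array(ifelse(vox == 0L, 0, Inf), dim = d)
  d_lum <- sqrt(.cpp_gdt(f_lum, d))
  d_tis <- sqrt(.cpp_gdt(f_tis, d))
  phi <- ifelse(vox == 1L, -d_tis, d_lum) * occ$spacing[1]
  structure(list(phi = phi, spacing = occ$spacing,
                 z_center_index = occ$z_center_index),
            class = "level_set")
}

#' Solid indicator for volume penalization
#'
#' Maps the signed distance to the penalization mask `chi` in `[0, 1]`
#' (1 = tissue, 0 = lumen).  `smoothing_width = 0` gives the hard
#' indicator `chi = 1(phi > 0)`; a width `w` gives a linear ramp over
#' `phi` in `[-w dx, +w dx]`, smearing the wall over about `2 w` cells
#' and placing `chi = 0.5` on the interface.
#'
#' @param ls a `level_set`.
#' @param smoothing_width ramp half-width in cells, >= 0.
#' @return object of class `solid_indicator`: `chi` (3D array),
#'   `spacing`, `smoothing_width`, `z_center_index`.
#' @export
solid_indicator <- function(ls, smoothing_width = 1) {
  stopifnot(inherits(ls, "level_set"))
  if (smoothing_width < 0) stop("smoothing_width must be >= 0")
  dx <- ls$spacing[1]
  chi <- if (smoothing_width == 0) {
    (ls$phi > 0) + 0
  } else {
    clamp(0.5 + ls$phi / (2 * smoothing_width * dx), 0, 1)
  }
  structure(list(chi = chi, spacing = ls$spacing,
                 smoothing_width = smoothing_width,
                 z_center_index = ls$z_center_index),
            class = "solid_indicator")
}

#' Reconstruct solver geometry from a 2D mask in one call
#'
#' Convenience wrapper: radius field, sphere-envelope occupancy, signed
#' distance and solid indicator.
#'
#' @param mask a [vessel_mask()].
#' @param smoothing_width passed to [solid_indicator()].
#' @return list with `radius`, `occupancy`, `level_set`, `solid`.
#' @export
reconstruct_geometry <- function(mask, smoothing_width = 1) {
  radius <- local_radius_field(mask)
  occ <- build_occupancy(radius)
  ls <- compute_level_set(occ)
  solid <- solid_indicator(ls, smoothing_width)
  list(radius = radius, occupancy = occ, level_set = ls, solid = solid)
}
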