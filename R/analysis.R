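#' Womersley number
#'
#' `alpha = d * sqrt(omega / nu)`: the ratio of the viscous wall-to-bulk
#' momentum propagation time to the pulsation period.  `alpha << 1`
#' justifies treating pulsatile microvascular flow as quasi-steady.
#'
#' @param d vessel diameter (m).
#' @param omega heart-rate angular frequency (1/s).
#' @param nu kinematic viscosity (m^2/s).
#' @return the dimensionless Womersley number.
#' @export
womersley <- function(d, omega, nu) {
  if (any(c(d, omega, nu) <= 0)) stop("all inputs must be positive")
  d * sqrt(omega / nu)
}

#' Peclet number
#'
#' `Pe = u * L / D`: ratio of convective to diffusive transport.
#'
#' @param u velocity scale (m/s).
#' @param L length scale (m).
#' @param D molecular diffusivity (m^2/s).
#' @return the dimensionless Peclet number.
#' @export
peclet <- function(u, L, D) {
  if (any(c(L, D) <= 0) || any(u < 0)) stop("inputs must be positive")
  u * L / D
}

#' Cylindrical analysis frame
#'
#' Defines the `(r, theta)` system used to decompose velocities into
#' radial and azimuthal components: origin at the first branching point
#' near the inlet, with the positive azimuthal direction oriented from
#' the artery toward the vein.
#'
#' @param origin `(x0, y0)` in micrometres (physical coordinates; cell
#'   centers sit at `(i - 0.5) * spacing`).
#' @param theta_artery,theta_vein ray angles (radians) of the artery and
#'   vein directions from the origin; used only to fix the sign of the
#'   azimuthal unit vector.
#' @param R_max optional; distance of the farthest lumen voxel from the
#'   origin (micrometres).  Computed by [partition_regions()] when
#'   `NULL`.
#' @return object of class `cylindrical_frame`.
#' @export
cylindrical_frame <- function(origin, theta_artery, theta_vein,
                              R_max = NULL) {
  stopifnot(length(origin) == 2)
  dth <- theta_vein - theta_artery
  # wrap to (-pi, pi]: positive rotation artery -> vein?
  dth <- atan2(sin(dth), cos(dth))
  orient <- if (dth >= 0) 1 else -1
  structure(list(origin = as.numeric(origin),
                 theta_artery = theta_artery, theta_vein = theta_vein,
                 orientation = orient, R_max = R_max),
            class = "cylindrical_frame")
}

frame_rtheta <- function(frame, spacing, N) {
  xc <- (seq_len(N[1]) - 0.5) * spacing - frame$origin[1]
  yc <- (seq_len(N[2]) - 0.5) * spacing - frame$origin[2]
  X <- matrix(xc, N[1], N[2])
  Y <- matrix(yc, N[1], N[2], byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  list(X = X, Y = Y, r = r)
}

#' Cylindrical velocity decomposition
#'
#' Transforms cell-centered `(u, v)` into radial and azimuthal
#' components about the frame origin: `u_r = u . e_r`,
#' `u_theta = u . e_theta` with `e_theta` oriented artery-to-vein
#' positive.  The z component is untouched; cells at exactly `r = 0`
#' get `u_r = u_theta = 0`.
#'
#' @param flow a `steady_flow`.
#' @param frame a [cylindrical_frame()].
#' @return list of 3D arrays `u_r`, `u_theta` and the in-plane radius
#'   matrix `r` (micrometres).
#' @export
to_cylindrical <- function(flow, frame) {
  cc <- cell_velocity(flow)
  N <- dim(cc$u)
  g <- frame_rtheta(frame, flow$grid$spacing, N)
  r <- g$r
  cs <- ifelse(r > 0, g$X / r, 0)
  sn <- ifelse(r > 0, g$Y / r, 0)
  ur <- array(0, N); ut <- array(0, N)
  for (k in seq_len(N[3])) {
    ur[, , k] <- cc$u[, , k] * cs + cc$v[, , k] * sn
    ut[, , k] <- frame$orientation *
      (-cc$u[, , k] * sn + cc$v[, , k] * cs)
  }
  list(u_r = ur, u_theta = ut, r = r)
}

#' Radial region partition
#'
#' Labels every lumen cell by the annulus its radius falls in, with
#' breakpoints at `fractions * R_max`.  `fractions = 0.7` gives the
#' inner-plexus / angiogenic-front split (the front is
#' `0.7 R_max < r <= R_max`); `c(0.3, 0.7)` gives the three-region
#' inner/middle/outer variant.
#'
#' @param occ an `occupancy_grid` (or 0/1 3D array) marking lumen cells.
#' @param frame a [cylindrical_frame()].
#' @param fractions strictly increasing breakpoints in (0, 1).
#' @param spacing voxel spacing (micrometres); taken from `occ` when it
#'   is an `occupancy_grid`.
#' @return object of class `region_partition`: integer `labels` array
#'   (0 = tissue, 1..n regions inside-out), `R_max`, `fractions`,
#'   per-region lumen cell counts `n_cells`.
#' @export
partition_regions <- function(occ, frame, fractions = 0.7,
                              spacing = NULL) {
  vox <- if (inherits(occ, "occupancy_grid")) occ$voxels else occ
  spacing <- spacing %||% (if (inherits(occ, "occupancy_grid"))
    occ$spacing[1] else stop("spacing required"))
  if (any(diff(c(0, fractions, 1)) <= 0))
    stop("fractions must be strictly increasing within (0, 1)")
  if (sum(vox) == 0) stop("empty lumen")
  N <- dim(vox)
  g <- frame_rtheta(frame, spacing, N[1:2])
  lum2d <- apply(vox == 1L, c(1, 2), any)
  R_max <- frame$R_max %||% max(g$r[lum2d])
  breaks <- c(0, fractions * R_max, R_max * (1 + 1e-12))
  lab2d <- matrix(findInterval(g$r, breaks, left.open = TRUE,
                               rightmost.closed = TRUE),
                  N[1], N[2])
  lab2d[lab2d > length(fractions) + 1] <- length(fractions) + 1L
  lab2d[g$r == 0] <- 1L  # origin cell belongs to the innermost region
  labels <- array(0L, N)
  for (k in seq_len(N[3]))
    labels[, , k] <- lab2d * (vox[, , k] == 1L)
  n_regions <- length(fractions) + 1L
  n_cells <- tabulate(labels[labels > 0L], nbins = n_regions)
  structure(list(labels = labels, R_max = R_max, fractions = fractions,
                 n_cells = n_cells, spacing = spacing),
            class = "region_partition")
}

#' Azimuthal flow rates per region
#'
#' Volume integrals of the azimuthal velocity over the lumen cells of
#' each radial region: `Q_theta(region) = sum u_theta * dV`
#' (nondimensional).  Three normalizations are reported: the raw
#' integral, the per-unit-fluid-volume mean, and the integral divided by
#' the inlet volumetric flux times the inlet diameter (both
#' nondimensional, so the divisor is the nondimensional inlet flux).
#'
#' @param u_theta cell-centered azimuthal velocity array (from
#'   [to_cylindrical()]).
#' @param partition a [partition_regions()] result.
#' @param flow the `steady_flow` the velocities came from (supplies the
#'   cell volume and inlet flux).
#' @return object of class `azimuthal_flow_report`: a data frame
#'   `regions` with columns `region`, `fluid_volume`, `Q_theta_raw`,
#'   `Q_theta_per_volume`, `Q_theta_normalized`, plus `Q_total`.
#' @export
azimuthal_flow_rate <- function(u_theta, partition, flow) {
  h <- flow$h
  dV <- h^3
  labs <- partition$labels
  n_regions <- length(partition$fractions) + 1L
  Q <- vapply(seq_len(n_regions), function(g)
    sum(u_theta[labs == g]) * dV, numeric(1))
  vol <- partition$n_cells * dV
  qn <- Q / (flow$flux_in * 1)  # inlet flux x D_in, both nondimensional
  qpv <- ifelse(vol > 0, Q / vol, 0)
  df <- data.frame(
    region = seq_len(n_regions),
    fluid_volume = vol,
    Q_theta_raw = Q,
    Q_theta_per_volume = qpv,
    Q_theta_normalized = qn)
  structure(list(regions = df, Q_total = sum(Q),
                 R_max = partition$R_max), class = "azimuthal_flow_report")
}

#' @export
print.azimuthal_flow_report <- function(x, ...) {
  cat("azimuthal flow report (regions inside-out):\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("total Q_theta: %.4g (R_max %.4g um)\n", x$Q_total, x$R_max))
  invisible(x)
}

#' Suggest an analysis origin from the mask skeleton
#'
#' Candidate origins are skeleton branch points; the suggestion is the
#' branch point closest to the inlet face (the first bifurcation along
#' the inlet vessel).
#'
#' @param mask a [vessel_mask()].
#' @param inlet_face which domain face carries the inlet (`"xlo"`,
#'   `"xhi"`, `"ylo"`, `"yhi"`).
#' @return `(x0, y0)` in micrometres.
#' @export
suggest_origin <- function(mask, inlet_face = "xlo") {
  sk <- skeletonize_mask(mask)
  nb <- .cpp_neighbor_counts(sk$pixels)
  bp <- which(!is.na(nb) & nb >= 3L, arr.ind = TRUE)
  if (nrow(bp) == 0) stop("skeleton has no branch points")
  d <- dim(mask$pixels)
  key <- switch(inlet_face,
                xlo = bp[, 1], xhi = d[1] - bp[, 1],
                ylo = bp[, 2], yhi = d[2] - bp[, 2],
                stop("unsupported inlet face"))
  sel <- bp[which.min(key), ]
  (as.numeric(sel) - 0.5) * mask$pixel_size
}
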