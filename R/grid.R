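#' Solver grid
#'
#' Uniform, isotropic Cartesian grid description.  Either wraps an
#' `occupancy_grid` exactly, or derives cell counts `N = round(L / dx)`
#' from a physical domain size.
#'
#' @param x an `occupancy_grid`, or a numeric length-3 domain size
#'   `(Lx, Ly, Lz)` in micrometres.
#' @param spacing grid spacing in micrometres (isotropic; default the
#'   occupancy spacing, or 1.51 for a physical domain).
#' @param D_in inlet artery diameter in micrometres (reference length
#'   for nondimensionalization).
#' @return object of class `solver_grid`: `N` (cells per axis), `L`
#'   (micrometres), `spacing`, `D_in`.
#' @export
make_grid <- function(x, spacing = NULL, D_in = NULL) {
  if (inherits(x, "occupancy_grid")) {
    spacing <- spacing %||% x$spacing[1]
    if (abs(spacing - x$spacing[1]) > 1e-9 * spacing)
      stop("requested spacing does not match the occupancy spacing")
    N <- dim(x$voxels)
    L <- N * spacing
  } else {
    if (!is.numeric(x) || length(x) != 3)
      stop("x must be an occupancy_grid or a length-3 domain size")
    spacing <- spacing %||% 1.51
    L <- x
    N <- as.integer(round(L / spacing))
    if (any(N < 1)) stop("domain smaller than one cell")
  }
  structure(list(N = as.integer(N), L = as.numeric(N * spacing),
                 spacing = spacing, D_in = D_in),
            class = "solver_grid")
}

#' @export
print.solver_grid <- function(x, ...) {
  cat(sprintf("solver_grid: %d x %d x %d cells, dx = %.4g um, L = %.4g x %.4g x %.4g um\n",
              x$N[1], x$N[2], x$N[3], x$spacing, x$L[1], x$L[2], x$L[3]))
  invisible(x)
}

#' Boundary patch
#'
#' A rectangular patch on one face of the domain box through which flow
#' enters or leaves.  `span` restricts the patch to index ranges in the
#' two in-face axes (cells, 1-based, inclusive); `NULL` means the whole
#' face.  Only boundary faces adjacent to lumen cells (solid indicator
#' `chi <= 0.5`) are open.
#'
#' @param face one of `"xlo"`, `"xhi"`, `"ylo"`, `"yhi"`, `"zlo"`,
#'   `"zhi"`.
#' @param span optional list of two integer ranges, e.g.
#'   `list(c(1, 40), c(1, 22))`, in the face's own (axis1, axis2) order:
#'   x-faces use (y, z), y-faces (x, z), z-faces (x, y).
#' @return object of class `boundary_patch`.
#' @export
boundary_patch <- function(face, span = NULL) {
  face <- match.arg(face, c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi"))
  structure(list(face = face, span = span), class = "boundary_patch")
}

#' Flow solver configuration
#'
#' @param Re Reynolds number built on the inlet bulk velocity and inlet
#'   diameter (default 0.1).
#' @param eta nondimensional penalization strength (default 1e4).
#' @param inlet,outlet [boundary_patch()]es; exactly one of each.
#' @param dt fixed nondimensional pseudo-time step, or `NULL` for
#'   CFL-based adaptive stepping.
#' @param cfl convective CFL number used when `dt` is `NULL`
#'   (default 0.2).
#' @param dt_diff_coeff diffusive cap coefficient for the adaptive
#'   step, `dt <= dt_diff_coeff * h^2 * Re` (default 1.3); keeps the
#'   factored Crank-Nicolson operator near-exact so pseudo-time
#'   convergence is not throttled by splitting error.
#' @param steady_tol steady-state residual threshold on
#'   `max |du| / dt` (default 1e-6), sustained over `persist` steps.
#' @param persist consecutive steps below `steady_tol` required
#'   (default 10).
#' @param poisson_tol relative residual for the pressure Poisson solve
#'   (default 1e-8).
#' @param max_steps pseudo-time step cap.
#' @param poisson_max_cycles multigrid V-cycle cap per solve.
#' @param verbose print residuals every this many steps (0 = quiet).
#' @return object of class `flow_config`.
#' @export
flow_config <- function(Re = 0.1, eta = 1e4,
                        inlet = boundary_patch("xlo"),
                        outlet = boundary_patch("xhi"),
                        dt = NULL, cfl = 0.2, dt_diff_coeff = 1.3,
                        steady_tol = 1e-6, persist = 10,
                        poisson_tol = 1e-8, max_steps = 20000,
                        poisson_max_cycles = 60, verbose = 0) {
  stopifnot(Re > 0, eta > 0, inherits(inlet, "boundary_patch"),
            inherits(outlet, "boundary_patch"))
  structure(list(Re = Re, eta = eta, inlet = inlet, outlet = outlet,
                 dt = dt, cfl = cfl, dt_diff_coeff = dt_diff_coeff,
                 steady_tol = steady_tol,
                 persist = persist, poisson_tol = poisson_tol,
                 max_steps = max_steps,
                 poisson_max_cycles = poisson_max_cycles,
                 verbose = verbose),
            class = "flow_config")
}

# face bookkeeping: for each face, the boundary array it lives in and
# the in-face dims (a1, a2) in storage order
face_info <- function(face, N) {
  switch(face,
    xlo = list(arr = "ubc_lo", a = c(N[2], N[3]), sign = +1, axis = 1),
    xhi = list(arr = "ubc_hi", a = c(N[2], N[3]), sign = -1, axis = 1),
    ylo = list(arr = "vbc_lo", a = c(N[1], N[3]), sign = +1, axis = 2),
    yhi = list(arr = "vbc_hi", a = c(N[1], N[3]), sign = -1, axis = 2),
    zlo = list(arr = "wbc_lo", a = c(N[1], N[2]), sign = +1, axis = 3),
    zhi = list(arr = "wbc_hi", a = c(N[1], N[2]), sign = -1, axis = 3))
}

# chi slice adjacent to a face, [a1, a2]
face_chi <- function(chi, face) {
  N <- dim(chi)
  switch(face,
    xlo = chi[1, , ], xhi = chi[N[1], , ],
    ylo = chi[, 1, ], yhi = chi[, N[2], ],
    zlo = chi[, , 1], zhi = chi[, , N[3]])
}

face_open <- function(chi, patch) {
  sl <- face_chi(chi, patch$face)
  open <- sl <= 0.5
  if (!is.null(patch$span)) {
    keep <- matrix(FALSE, nrow(open), ncol(open))
    r1 <- patch$span[[1]]; r2 <- patch$span[[2]]
    keep[r1[1]:r1[2], r2[1]:r2[2]] <- TRUE
    open <- open & keep
  }
  open
}

#' Boundary face velocities for an inlet/outlet configuration
#'
#' Builds the six boundary-face normal-velocity arrays: uniform unit
#' inward speed over the open (lumen-adjacent) inlet faces, outward
#' outlet speed scaled by the open-area ratio so that the volumetric
#' flux balances exactly, zero elsewhere.
#'
#' @param chi 3D solid-indicator array.
#' @param config a [flow_config()].
#' @return list with the six face arrays (`ubc_lo`, `ubc_hi`, `vbc_lo`,
#'   `vbc_hi`, `wbc_lo`, `wbc_hi`), open face counts `n_in`, `n_out`
#'   and the outlet speed `U_out`.
#' @export
boundary_values <- function(chi, config) {
  N <- dim(chi)
  bv <- list(ubc_lo = matrix(0, N[2], N[3]), ubc_hi = matrix(0, N[2], N[3]),
             vbc_lo = matrix(0, N[1], N[3]), vbc_hi = matrix(0, N[1], N[3]),
             wbc_lo = matrix(0, N[1], N[2]), wbc_hi = matrix(0, N[1], N[2]))
  if (config$inlet$face == config$outlet$face &&
      is.null(config$inlet$span) && is.null(config$outlet$span))
    stop("inlet and outlet patches coincide")
  open_in <- face_open(chi, config$inlet)
  open_out <- face_open(chi, config$outlet)
  n_in <- sum(open_in); n_out <- sum(open_out)
  if (n_in == 0) stop("inlet patch has no lumen overlap")
  if (n_out == 0) stop("outlet patch has no lumen overlap")
  U_out <- n_in / n_out
  fi <- face_info(config$inlet$face, N)
  fo <- face_info(config$outlet$face, N)
  bv[[fi$arr]][open_in] <- fi$sign * 1
  # outward flow: positive normal component on hi faces, negative on lo
  bv[[fo$arr]][open_out] <- bv[[fo$arr]][open_out] + (-fo$sign) * U_out
  c(bv, list(n_in = n_in, n_out = n_out, U_out = U_out))
}

#' Apply boundary conditions to a staggered flow state
#'
#' Sets the Dirichlet boundary-face normal velocities (inlet plug,
#' flux-balancing outlet, zero elsewhere) on the staggered arrays of
#' `state`.  Pressure boundary conditions are Neumann and are handled
#' inside the stencils.
#'
#' @param state list with staggered arrays `u`, `v`, `w` (and `p`).
#' @param chi 3D solid-indicator array.
#' @param config a [flow_config()].
#' @return the state with boundary faces set; attribute `"bv"` carries
#'   the boundary-value structure.
#' @export
apply_boundary_conditions <- function(state, chi, config) {
  N <- dim(chi)
  bv <- boundary_values(chi, config)
  state$u[1, , ] <- bv$ubc_lo
  state$u[N[1] + 1, , ] <- bv$ubc_hi
  state$v[, 1, ] <- bv$vbc_lo
  state$v[, N[2] + 1, ] <- bv$vbc_hi
  state$w[, , 1] <- bv$wbc_lo
  state$w[, , N[3] + 1] <- bv$wbc_hi
  attr(state, "bv") <- bv
  state
}

#' Empty staggered flow state
#'
#' @param N cell counts `(Nx, Ny, Nz)`.
#' @return list of zero arrays `u` (x-faces), `v` (y-faces), `w`
#'   (z-faces), `p` (cell centers).
#' @export
new_flow_state <- function(N) {
  list(u = array(0, c(N[1] + 1L, N[2], N[3])),
       v = array(0, c(N[1], N[2] + 1L, N[3])),
       w = array(0, c(N[1], N[2], N[3] + 1L)),
       p = array(0, c(N[1], N[2], N[3])))
}
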