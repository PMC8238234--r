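# R-facing wrappers around the compiled staggered-grid kernels.  All
# operators take/return arrays shaped like the staggered layout of
# new_flow_state(); nondimensional units throughout (lengths by the
# inlet diameter, velocities by the inlet bulk speed).

#' Convective tendency (divergence-form central differences)
#'
#' Energy-conservative second-order central discretization of
#' `-d(u_i u_j)/dx_j` on the staggered grid; evaluated on interior
#' faces, zero on Dirichlet boundary faces.
#'
#' @param state staggered flow state (`u`, `v`, `w`).
#' @param h nondimensional grid spacing.
#' @return list of face-centered tendency arrays `u`, `v`, `w`.
#' @export
convective_tendency <- function(state, h) {
  N <- dim(state$p) %||% c(dim(state$u)[1] - 1L, dim(state$u)[2],
                           dim(state$u)[3])
  .cpp_conv_tendency(state$u, state$v, state$w, as.integer(N), h)
}

#' Diffusive tendency (7-point Laplacian / Re)
#'
#' @inheritParams convective_tendency
#' @param Re Reynolds number.
#' @return list of face-centered tendency arrays.
#' @export
diffusive_tendency <- function(state, h, Re) {
  N <- dim(state$p) %||% c(dim(state$u)[1] - 1L, dim(state$u)[2],
                           dim(state$u)[3])
  .cpp_diff_tendency(state$u, state$v, state$w, as.integer(N), h, Re)
}

#' Penalization tendency
#'
#' The volume-penalization body force `-eta * chi * u` with the solid
#' indicator averaged arithmetically to faces.
#'
#' @inheritParams convective_tendency
#' @param chi 3D cell-centered solid indicator in `[0, 1]`.
#' @param eta penalization strength, > 0.
#' @return list of face-centered tendency arrays.
#' @export
penalization_tendency <- function(state, chi, eta) {
  if (eta <= 0) stop("eta must be positive")
  cf <- .cpp_chi_faces(chi, dim(chi))
  list(u = -eta * cf$u * state$u,
       v = -eta * cf$v * state$v,
       w = -eta * cf$w * state$w)
}

#' Discrete divergence of a staggered velocity field
#'
#' @inheritParams convective_tendency
#' @return cell-centered array.
#' @export
flow_divergence <- function(state, h) {
  N <- dim(state$p) %||% c(dim(state$u)[1] - 1L, dim(state$u)[2],
                           dim(state$u)[3])
  .cpp_divergence(state$u, state$v, state$w, as.integer(N), h)
}

#' Pressure Poisson solve (pure Neumann)
#'
#' Solves `Lap p = rhs` on the cell-centered grid with homogeneous
#' Neumann boundaries, pinned to zero mean.  Compatibility is enforced
#' by subtracting the rhs mean.  Geometric multigrid with a
#' conjugate-gradient fallback, or plain CG.
#'
#' @param rhs cell-centered right-hand side (3D array).
#' @param h grid spacing.
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_cycles V-cycle (or CG iteration) cap.
#' @param method `"mg"` (default) or `"cg"`.
#' @return list with `x` (zero-mean solution), `relres`, `iters`.
#' @export
pressure_poisson_solve <- function(rhs, h, tol = 1e-8, max_cycles = 60,
                                   method = c("mg", "cg")) {
  method <- match.arg(method)
  mc <- if (method == "cg") max(max_cycles, 10000L) else max_cycles
  res <- .cpp_poisson(rhs, dim(rhs), h, tol, as.integer(mc), method)
  if (res$relres > tol)
    warning(sprintf("pressure Poisson solve reached relres %.2e > tol %.2e",
                    res$relres, tol))
  res
}

solver_geometry_check <- function(chi, grid) {
  if (!is.array(chi) || length(dim(chi)) != 3)
    stop("chi must be a 3D array")
  if (!all(dim(chi) == grid$N))
    stop("chi dimensions do not match the solver grid")
  if (is.null(grid$D_in) || grid$D_in <= 0)
    stop("grid needs a positive inlet diameter D_in for nondimensionalization")
}

face_cell_indices <- function(open, face, N) {
  idx <- which(open, arr.ind = TRUE)
  cells <- switch(face,
    xlo = cbind(1L, idx), xhi = cbind(N[1], idx),
    ylo = cbind(idx[, 1], 1L, idx[, 2]),
    yhi = cbind(idx[, 1], N[2], idx[, 2]),
    zlo = cbind(idx, 1L), zhi = cbind(idx, N[3]))
  (cells[, 3] - 1L) * N[1] * N[2] + (cells[, 2] - 1L) * N[1] + cells[, 1]
}

check_lumen_connected <- function(chi, config) {
  N <- dim(chi)
  fluid <- array(as.integer(chi <= 0.5), N)
  seeds <- face_cell_indices(face_open(chi, config$inlet),
                             config$inlet$face, N)
  reach <- .cpp_reachable3d(fluid, N, as.integer(seeds))
  out_cells <- face_cell_indices(face_open(chi, config$outlet),
                                 config$outlet$face, N)
  if (!any(reach[out_cells]))
    stop("disconnected lumen: no fluid path links the inlet and outlet ",
         "patches, so the imposed fluxes cannot balance physically")
  invisible(TRUE)
}

run_solver <- function(chi, grid, config, init = NULL, max_steps = NULL) {
  solver_geometry_check(chi, grid)
  h <- grid$spacing / grid$D_in
  bv <- boundary_values(chi, config)
  check_lumen_connected(chi, config)
  dt_in <- config$dt %||% -1
  res <- .cpp_solve(chi, as.integer(grid$N), h, config$Re, config$eta,
                    dt_in, config$cfl, config$dt_diff_coeff %||% 1.3,
                    as.integer(max_steps %||% config$max_steps),
                    config$steady_tol, as.integer(config$persist),
                    config$poisson_tol,
                    as.integer(config$poisson_max_cycles),
                    bv$ubc_lo, bv$ubc_hi, bv$vbc_lo, bv$vbc_hi,
                    bv$wbc_lo, bv$wbc_hi,
                    init, as.integer(config$verbose))
  if (res$blown_up)
    stop("flow solver diverged (non-finite residual); reduce dt/cfl")
  h2 <- h * h
  flux_in <- bv$n_in * 1 * h2
  flux_out <- bv$n_out * bv$U_out * h2
  structure(list(
    u = res$u, v = res$v, w = res$w, p = res$p,
    step = res$steps, residual = tail_or_na(res$residual_history),
    residual_history = res$residual_history,
    converged = res$converged, dt = res$dt,
    div_max = res$div_max, poisson_relres = res$poisson_relres,
    flux_in = flux_in, flux_out = flux_out,
    n_in = bv$n_in, n_out = bv$n_out, U_out = bv$U_out,
    chi = chi, grid = grid, config = config, h = h),
    class = "steady_flow")
}

tail_or_na <- function(x) if (length(x)) x[length(x)] else NA_real_

#' Advance the penalized Navier-Stokes system by pseudo-time steps
#'
#' One (or a few) full SMAC fractional steps: three low-storage RK3
#' substeps with Crank-Nicolson diffusion (delta-form approximate
#' factorization) and implicit penalization, then a single pressure
#' projection.
#'
#' @param state staggered state from [new_flow_state()] (boundary faces
#'   are (re)imposed from the config).
#' @param chi cell-centered solid indicator array.
#' @param grid a [make_grid()] with `D_in` set.
#' @param config a [flow_config()]; `config$dt` must be set for
#'   single-step use if a fixed step is wanted.
#' @param n number of full steps to take.
#' @return a `steady_flow` object after `n` steps (converged or not).
#' @export
time_step <- function(state, chi, grid, config, n = 1) {
  cfg <- config
  cfg$steady_tol <- -1  # never stop early
  run_solver(chi, grid, cfg, init = state, max_steps = n)
}

#' March the penalized flow to steady state
#'
#' Pseudo-time advances from rest (or `init`) until the residual
#' `max |u^{n+1} - u^n| / dt` stays at or below `config$steady_tol`
#' for `config$persist` consecutive steps, or `max_steps` is reached
#' (with a warning).
#'
#' @param chi cell-centered solid indicator array (1 = tissue).
#' @param grid a [make_grid()] with `D_in` set.
#' @param config a [flow_config()].
#' @param init optional initial state.
#' @return object of class `steady_flow`: staggered `u`, `v`, `w`, `p`,
#'   residual history, convergence flag, inlet/outlet fluxes, and the
#'   inputs (`chi`, `grid`, `config`).
#' @export
run_to_steady_state <- function(chi, grid, config = flow_config(),
                                init = NULL) {
  out <- run_solver(chi, grid, config, init = init)
  if (!out$converged)
    warning(sprintf(
      "solver did not reach steady_tol %.1e in %d steps (residual %.2e)",
      config$steady_tol, out$step, out$residual))
  out
}

#' @export
print.steady_flow <- function(x, ...) {
  cat(sprintf(paste0(
    "steady_flow: %d x %d x %d cells, %d steps, residual %.2e (%s)\n",
    "  flux in %.4g, out %.4g, max |div| %.2e\n"),
    x$grid$N[1], x$grid$N[2], x$grid$N[3], x$step, x$residual,
    if (x$converged) "converged" else "NOT converged",
    x$flux_in, x$flux_out, x$div_max))
  invisible(x)
}

#' Cell-centered velocity components of a staggered flow field
#'
#' Arithmetic average of the two bounding faces per component.
#'
#' @param flow a `steady_flow` (or any staggered state with `u,v,w`).
#' @return list of 3D arrays `u`, `v`, `w`, `speed`.
#' @export
cell_velocity <- function(flow) {
  u <- flow$u; v <- flow$v; w <- flow$w
  nx <- dim(u)[1] - 1L; ny <- dim(v)[2] - 1L; nz <- dim(w)[3] - 1L
  uc <- 0.5 * (u[1:nx, , , drop = FALSE] + u[2:(nx + 1), , , drop = FALSE])
  vc <- 0.5 * (v[, 1:ny, , drop = FALSE] + v[, 2:(ny + 1), , drop = FALSE])
  wc <- 0.5 * (w[, , 1:nz, drop = FALSE] + w[, , 2:(nz + 1), drop = FALSE])
  list(u = uc, v = vc, w = wc, speed = sqrt(uc^2 + vc^2 + wc^2))
}
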