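#' Pipeline configuration
#'
#' A single structured configuration driving all stages: mask ingestion,
#' 3D reconstruction, flow solve and azimuthal analysis.  Defaults
#' follow the retinal A-V setup: 1.51 um grid spacing, Re = 0.1,
#' penalization 1e4, angiogenic-front breakpoint at 0.7 R_max.
#'
#' @param mask_path raster file of the vessel mask (PGM/CSV), or `NA`
#'   when a mask object is passed to [run_pipeline()] directly.
#' @param pixel_size micrometres per pixel of the input mask.
#' @param spacing solver grid spacing (um); the mask is resampled to
#'   this resolution before reconstruction.
#' @param threshold binarization threshold fraction.
#' @param Re,eta,smoothing_width,steady_tol,poisson_tol,max_steps solver
#'   parameters, see [flow_config()] and [solid_indicator()].
#' @param inlet,outlet [boundary_patch()] specs (or lists
#'   `list(face=, span=)`).
#' @param D_in inlet artery diameter (um); `NULL` to take it from the
#'   mask metadata or, failing that, twice the largest local radius.
#' @param origin analysis origin `(x0, y0)` in um; `NULL` to use mask
#'   metadata or the first skeleton branch point near the inlet.
#' @param theta_artery,theta_vein ray angles (radians) fixing the
#'   azimuthal sign; defaults lean on mask metadata or `+/- pi/4`.
#' @param fractions radial breakpoints for the region partition.
#' @param seed RNG seed recorded in the provenance record.
#' @param write_vtk,write_png output toggles.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mask_path = NA_character_,
                            pixel_size = 1.51,
                            spacing = 1.51,
                            threshold = 0.5,
                            Re = 0.1, eta = 1e4, smoothing_width = 1,
                            steady_tol = 1e-6, poisson_tol = 1e-8,
                            max_steps = 20000,
                            inlet = boundary_patch("xlo"),
                            outlet = boundary_patch("xlo"),
                            D_in = NULL,
                            origin = NULL,
                            theta_artery = NULL, theta_vein = NULL,
                            fractions = 0.7,
                            seed = 1L,
                            write_vtk = TRUE, write_png = FALSE) {
  as_patch <- function(p) if (inherits(p, "boundary_patch")) p else
    boundary_patch(p$face, p$span)
  structure(list(mask_path = mask_path, pixel_size = pixel_size,
                 spacing = spacing, threshold = threshold, Re = Re,
                 eta = eta, smoothing_width = smoothing_width,
                 steady_tol = steady_tol, poisson_tol = poisson_tol,
                 max_steps = max_steps,
                 inlet = as_patch(inlet), outlet = as_patch(outlet),
                 D_in = D_in, origin = origin,
                 theta_artery = theta_artery, theta_vein = theta_vein,
                 fractions = fractions, seed = as.integer(seed),
                 write_vtk = write_vtk, write_png = write_png),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm_span <- function(s) {
    if (is.null(s) || length(s) == 0) return(NULL)
    if (is.matrix(s)) return(list(s[1, ], s[2, ]))
    lapply(s, as.numeric)
  }
  x$inlet <- boundary_patch(x$inlet$face, norm_span(x$inlet$span))
  x$outlet <- boundary_patch(x$outlet$face, norm_span(x$outlet$span))
  do.call(pipeline_config, x[names(x) %in% names(formals(pipeline_config))])
}

stage_msg <- function(quiet, ...) if (!quiet) message("[angioflow] ", ...)

#' Run the full image-to-perfusion pipeline
#'
#' Morphometry, 3D reconstruction, penalized flow solve and azimuthal
#' flow analysis, with all reports and fields written into `out_dir`:
#' `morphometry.csv`, `azimuthal_flow.csv`, `fields.vtk`,
#' `residual_log.txt`, `config.json` and `provenance.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param mask optional [vessel_mask()] (skips reading
#'   `config$mask_path`).
#' @param quiet suppress stage messages.
#' @return list with `morphometry`, `flow`, `report`, `frame`,
#'   `partition`, `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, mask = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  # -- mask ------------------------------------------------------------
  if (is.null(mask)) {
    stage_msg(quiet, "loading mask ", config$mask_path)
    mask <- tryCatch(load_mask(config$mask_path, config$pixel_size,
                               threshold = config$threshold),
                     error = function(e) fail("load_mask", e))
  }
  # -- morphometry -----------------------------------------------------
  stage_msg(quiet, "morphometry")
  morpho <- tryCatch(morphometry(mask), error = function(e)
    fail("morphometry", e))
  write_morphometry_csv(morpho, file.path(out_dir, "morphometry.csv"),
                        sample_id = basename(config$mask_path %||% "mask"))
  # -- reconstruction --------------------------------------------------
  stage_msg(quiet, "3D reconstruction")
  geom <- tryCatch({
    m <- if (abs(mask$pixel_size - config$spacing) >
             1e-9 * config$spacing) {
      resample_mask(mask, config$spacing)
    } else mask
    reconstruct_geometry(m, smoothing_width = config$smoothing_width)
  }, error = function(e) fail("reconstruction", e))
  spec <- attr(mask, "spec")
  D_in <- config$D_in %||% spec$inlet_diameter %||% (2 * max(geom$radius$r))
  grid <- make_grid(geom$occupancy, D_in = D_in)
  # -- flow solve ------------------------------------------------------
  stage_msg(quiet, "flow solve (", paste(grid$N, collapse = " x "),
            " cells)")
  fc <- flow_config(Re = config$Re, eta = config$eta,
                    inlet = config$inlet, outlet = config$outlet,
                    steady_tol = config$steady_tol,
                    poisson_tol = config$poisson_tol,
                    max_steps = config$max_steps)
  flow <- tryCatch(run_to_steady_state(geom$solid$chi, grid, fc),
                   error = function(e) fail("flow_solver", e))
  writeLines(sprintf("%d %.6e", seq_along(flow$residual_history),
                     flow$residual_history),
             file.path(out_dir, "residual_log.txt"))
  # -- analysis --------------------------------------------------------
  stage_msg(quiet, "azimuthal flow analysis")
  origin <- config$origin %||% attr(mask, "origin") %||%
    suggest_origin(mask, config$inlet$face)
  th_a <- config$theta_artery %||% attr(mask, "theta_artery") %||% (pi / 4)
  th_v <- config$theta_vein %||% attr(mask, "theta_vein") %||% (-pi / 4)
  frame <- cylindrical_frame(origin, th_a, th_v)
  part <- tryCatch(partition_regions(geom$occupancy, frame,
                                     fractions = config$fractions),
                   error = function(e) fail("flow_analysis", e))
  cyl <- to_cylindrical(flow, frame)
  report <- azimuthal_flow_rate(cyl$u_theta, part, flow)
  utils::write.csv(report$regions,
                   file.path(out_dir, "azimuthal_flow.csv"),
                   row.names = FALSE)
  # -- fields & provenance --------------------------------------------
  if (isTRUE(config$write_vtk)) {
    cc <- cell_velocity(flow)
    logspeed <- log10(pmax(cc$speed, 1e-16))
    tryCatch(write_vtk(
      list(velocity = list(cc$u, cc$v, cc$w),
           log10_speed = logspeed,
           pressure = flow$p,
           chi = geom$solid$chi,
           phi = geom$level_set$phi,
           region = part$labels),
      file.path(out_dir, "fields.vtk"),
      spacing = grid$spacing,
      origin = rep(grid$spacing / 2, 3)),
      error = function(e) fail("vtk_output", e))
  }
  if (isTRUE(config$write_png)) {
    cc <- cell_velocity(flow)
    zmid <- geom$occupancy$z_center_index
    png_path <- file.path(out_dir, "log_speed_midplane.png")
    grDevices::png(png_path, width = 800, height = 800)
    graphics::image(log10(pmax(cc$speed[, , zmid], 1e-16)),
                    main = "log10 |u| / U_in, z = 0 plane",
                    useRaster = TRUE)
    grDevices::dev.off()
  }
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  prov <- list(
    package = "angioflow",
    version = as.character(utils::packageVersion("angioflow")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    grid = list(N = grid$N, spacing = grid$spacing, D_in = D_in),
    converged = flow$converged,
    steps = flow$step,
    residual = flow$residual)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(morphometry = morpho, flow = flow, report = report,
                 frame = frame, partition = part, geometry = geom,
                 out_dir = out_dir))
}
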