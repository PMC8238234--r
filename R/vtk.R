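#' Write fields as a legacy VTK structured-points file (ASCII)
#'
#' All fields must share one cell-centered 3D shape; vectors are given
#' as a list of three arrays.
#'
#' @param fields named list: each element a 3D array (scalar) or a list
#'   of three 3D arrays (vector components).
#' @param path output `.vtk` file.
#' @param spacing voxel spacing (micrometres, scalar or length 3).
#' @param origin physical origin of the first voxel center (length 3).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fields, path, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  first <- fields[[1]]
  dims <- if (is.list(first)) dim(first[[1]]) else dim(first)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "angioflow field output", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing[1], spacing[2],
                       spacing[3]),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {
      stopifnot(length(f) == 3)
      writeLines(sprintf("VECTORS %s float", nm), con)
      m <- cbind(as.numeric(f[[1]]), as.numeric(f[[2]]),
                 as.numeric(f[[3]]))
      writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3]), con)
    } else {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", as.numeric(f)), con)
    }
  }
  invisible(path)
}

#' Write a 3D array as flat binary with a small text header
#'
#' Produces `<prefix>.bin` (doubles, column-major) and `<prefix>.hdr`
#' (shape, spacing, z mid-plane index).
#'
#' @param a 3D array.
#' @param prefix output path prefix.
#' @param spacing voxel spacing (micrometres).
#' @param z_center_index index of the `z = 0` mid-plane (or `NA`).
#' @return the header path, invisibly.
#' @export
write_raw_field <- function(a, prefix, spacing, z_center_index = NA) {
  d <- dim(a)
  writeBin(as.numeric(a), paste0(prefix, ".bin"), size = 8,
           endian = "little")
  writeLines(c(paste("shape", paste(d, collapse = " ")),
               paste("spacing_um", paste(rep(spacing, length.out = 3),
                                         collapse = " ")),
               paste("z_center_index", z_center_index),
               "storage column-major float64 little-endian"),
             paste0(prefix, ".hdr"))
  invisible(paste0(prefix, ".hdr"))
}
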