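#' Vascular density
#'
#' Percentage of the analysis area occupied by vessel lumen.  The
#' denominator is the roi area when the mask carries an roi, otherwise
#' the full image.
#'
#' @param mask a [vessel_mask()].
#' @return percentage in `[0, 100]`.
#' @export
vascular_density <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  denom <- if (is.null(mask$roi)) length(mask$pixels) else sum(mask$roi)
  if (denom == 0) stop("zero-area analysis region")
  100 * sum(mask$pixels) / denom
}

#' Skeletonize a vessel mask
#'
#' Topological thinning (Zhang-Suen with a 2x2-block cleanup pass) down
#' to a 1-pixel-wide, 8-connected centerline.  The skeleton is a subset
#' of the lumen and preserves its connectivity.
#'
#' @param mask a [vessel_mask()].
#' @return an object of class `skeleton_mask` with fields `pixels` and
#'   `pixel_size`.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  sk <- .cpp_thin(mask$pixels)
  # Zhang-Suen erases tiny components outright (an isolated 2x2 block
  # vanishes); restore one representative pixel per lost component so
  # the skeleton preserves the component count
  lab <- .cpp_label2d(mask$pixels)
  ncomp <- max(lab)
  if (ncomp > 0) {
    has_sk <- tabulate(lab[sk == 1L], nbins = ncomp) > 0L
    for (g in which(!has_sk)) {
      idx <- which(lab == g)
      sk[idx[(length(idx) + 1L) %/% 2L]] <- 1L
    }
  }
  structure(list(pixels = sk, pixel_size = mask$pixel_size),
            class = "skeleton_mask")
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf("skeleton_mask: %d x %d px, %d skeleton px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Vessel length density
#'
#' Percentage of the analysis area occupied by the skeletonized vessel.
#'
#' @param skeleton a `skeleton_mask` derived from `mask`.
#' @param mask the source [vessel_mask()] (supplies the roi denominator).
#' @return percentage in `[0, 100]`.
#' @export
vessel_length_density <- function(skeleton, mask) {
  stopifnot(inherits(skeleton, "skeleton_mask"), inherits(mask, "vessel_mask"))
  denom <- if (is.null(mask$roi)) length(mask$pixels) else sum(mask$roi)
  if (denom == 0) stop("zero-area analysis region")
  100 * sum(skeleton$pixels) / denom
}

# unique 8-adjacency step lengths along a skeleton, in micrometres
skeleton_length_um <- function(px, pixel_size) {
  nx <- nrow(px); ny <- ncol(px)
  p <- px == 1L
  orth <- 0L; diag <- 0L
  if (nx > 1) orth <- orth + sum(p[-nx, ] & p[-1, ])
  if (ny > 1) orth <- orth + sum(p[, -ny] & p[, -1])
  if (nx > 1 && ny > 1) {
    diag <- diag + sum(p[-nx, -ny] & p[-1, -1])
    diag <- diag + sum(p[-1, -ny] & p[-nx, -1])
  }
  (orth + sqrt(2) * diag) * pixel_size
}

#' Branching index of a skeleton
#'
#' A branch point is a skeleton pixel with three or more skeleton
#' neighbours in 8-connectivity.  Total length sums unique adjacency
#' steps (orthogonal = `pixel_size`, diagonal = `sqrt(2) * pixel_size`)
#' and is reported in millimetres; the branching index is branch points
#' per millimetre of vessel length.
#'
#' @param skeleton a `skeleton_mask`.
#' @return list with `n_branch_points`, `total_length` (mm),
#'   `branching_index` (1/mm) and `degenerate` (`TRUE` when the skeleton
#'   has zero length, in which case the index is reported as 0).
#' @export
branching_index <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_mask"))
  nb <- .cpp_neighbor_counts(skeleton$pixels)
  n_bp <- sum(nb >= 3L, na.rm = TRUE)
  len_mm <- skeleton_length_um(skeleton$pixels, skeleton$pixel_size) / 1000
  if (len_mm > 0) {
    list(n_branch_points = n_bp, total_length = len_mm,
         branching_index = n_bp / len_mm, degenerate = FALSE)
  } else {
    list(n_branch_points = n_bp, total_length = 0,
         branching_index = 0, degenerate = TRUE)
  }
}

#' Morphometry report for a vessel mask
#'
#' Computes the three indices used to characterize branching phenotypes:
#' vascular density (area percentage of lumen), vessel length density
#' (area percentage of the skeleton) and branching index (branch points
#' per mm of centerline).
#'
#' @param mask a [vessel_mask()].
#' @param skeleton optional precomputed `skeleton_mask`.
#' @return object of class `morphometry_report`.
#' @export
morphometry <- function(mask, skeleton = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (is.null(skeleton)) skeleton <- skeletonize_mask(mask)
  bi <- branching_index(skeleton)
  structure(list(
    vascular_density = vascular_density(mask),
    vessel_length_density = vessel_length_density(skeleton, mask),
    branching_index = bi$branching_index,
    n_branch_points = bi$n_branch_points,
    total_length = bi$total_length,
    degenerate = bi$degenerate), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf(paste0(
    "morphometry: vascular density %.2f %%, length density %.2f %%,\n",
    "  branching index %.1f /mm (%d branch points over %.3f mm)\n"),
    x$vascular_density, x$vessel_length_density, x$branching_index,
    x$n_branch_points, x$total_length))
  invisible(x)
}

#' Write morphometry reports to CSV
#'
#' One row per sample: `sample_id, vascular_density,
#' vessel_length_density, branching_index, n_branch_points,
#' total_length_mm`.
#'
#' @param reports a `morphometry_report` or list of them.
#' @param path output CSV path.
#' @param sample_id character vector of ids (recycled names).
#' @return the data frame written, invisibly.
#' @export
write_morphometry_csv <- function(reports, path, sample_id = NULL) {
  if (inherits(reports, "morphometry_report")) reports <- list(reports)
  if (is.null(sample_id)) sample_id <- names(reports) %||%
      paste0("sample", seq_along(reports))
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(sample_id = sample_id[i],
               vascular_density = r$vascular_density,
               vessel_length_density = r$vessel_length_density,
               branching_index = r$branching_index,
               n_branch_points = r$n_branch_points,
               total_length_mm = r$total_length)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
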