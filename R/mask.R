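#' Binary vessel mask
#'
#' Container for a 2D binary lumen mask with a physical pixel size.
#' Pixels are stored in an integer matrix indexed as `pixels[x, y]` with
#' `x` the horizontal image axis and `y` increasing upward; pixel centers
#' sit at `(i - 0.5) * pixel_size` micrometres.  `1` marks lumen, `0`
#' surrounding tissue.  An optional `roi` (same shape) restricts the
#' analysis area, e.g. to the artery-vein wedge.
#'
#' @param pixels integer/logical matrix of 0/1 values, `[x, y]` indexed.
#' @param pixel_size micrometres per pixel (isotropic), > 0.
#' @param roi optional 0/1 matrix of the same shape; every lumen pixel
#'   must lie inside the roi.
#' @return an object of class `vessel_mask`.
#' @export
vessel_mask <- function(pixels, pixel_size, roi = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L))) stop("pixels must be binary (0/1)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (micrometres per pixel)")
  if (!is.null(roi)) {
    if (!is.matrix(roi) || !all(dim(roi) == dim(pixels)))
      stop("roi must be a matrix with the same dimensions as pixels")
    storage.mode(roi) <- "integer"
    if (!all(roi %in% c(0L, 1L))) stop("roi must be binary (0/1)")
    if (any(pixels == 1L & roi == 0L))
      stop("lumen pixels must lie inside the roi")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, roi = roi),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "vessel_mask: %d x %d px (%.4g x %.4g um), %.3g um/px, %d lumen px%s\n",
    d[1], d[2], d[1] * x$pixel_size, d[2] * x$pixel_size, x$pixel_size,
    sum(x$pixels), if (is.null(x$roi)) "" else ", with roi"))
  invisible(x)
}

# ---------------------------------------------------------------------
# raster I/O: portable anymap (PGM/PPM/PBM, ascii or binary) and CSV.
# No raster-image package is assumed; PGM is the plain-text interchange
# format used throughout.
# ---------------------------------------------------------------------

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  magic <- NULL
  # token scanner that skips comments; reads header only
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected end of file: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
        next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P1", "P2", "P3", "P5", "P6"))
    stop("unsupported raster format '", magic, "' in ", path,
         " (PGM/PPM expected)")
  nc <- as.integer(read_token())
  nr <- as.integer(read_token())
  maxval <- if (magic == "P1") 1L else as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- nr * nc * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval > 255) {
      readBin(con, "integer", n = n, size = 2, signed = FALSE,
              endian = "big")
    } else {
      as.integer(readBin(con, "raw", n = n))
    }
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated raster file: ", path)
  if (magic == "P1") vals <- 1L - vals  # PBM: 1 = black
  # row-major file order -> matrix [col along x], rows top-to-bottom
  if (nch == 3L) {
    a <- array(vals, dim = c(3, nc, nr))
    img <- aperm(a, c(2, 3, 1))
  } else {
    img <- array(vals, dim = c(nc, nr, 1))
  }
  list(img = img, maxval = maxval)
}

#' Write a binary mask or grayscale matrix as an ASCII PGM file
#'
#' @param x a `vessel_mask`, or an `[x, y]`-indexed numeric matrix.
#' @param path output file path (`.pgm`).
#' @param maxval intensity of a set pixel (default 255).
#' @export
write_pgm <- function(x, path, maxval = 255L) {
  m <- if (inherits(x, "vessel_mask")) x$pixels else x
  nx <- nrow(m); ny <- ncol(m)
  m2 <- if (max(m) > 0) round(m / max(m) * maxval) else m * 0
  storage.mode(m2) <- "integer"
  # our [x, y] (y up) -> raster rows top-to-bottom
  rows <- vapply(seq_len(ny), function(j)
    paste(m2[, ny - j + 1], collapse = " "), character(1))
  writeLines(c("P2", paste(nx, ny), as.character(maxval), rows), path)
  invisible(path)
}

#' Load a raster image and binarize it into a vessel mask
#'
#' Reads a single- or multi-channel raster (PGM/PPM/PBM, or a CSV/TSV
#' matrix of intensities), converts multi-channel data to grayscale by
#' channel averaging and binarizes at a fixed fraction of the dynamic
#' range (or by Otsu's method).
#'
#' @param path raster file (`.pgm`, `.ppm`, `.pbm`, `.pnm`, `.csv`,
#'   `.tsv`).
#' @param pixel_size micrometres per pixel.
#' @param threshold binarization threshold as a fraction of the dynamic
#'   range, in (0, 1).  Pixels strictly above `threshold * maxval`
#'   become lumen.
#' @param auto_threshold if `TRUE`, ignore `threshold` and use Otsu's
#'   method on the grayscale histogram.
#' @param roi optional roi matrix, see [vessel_mask()].
#' @return a [vessel_mask()].
#' @export
load_mask <- function(path, pixel_size, threshold = 0.5,
                      auto_threshold = FALSE, roi = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
    if (!is.numeric(m)) stop("non-numeric raster matrix in ", path)
    # file rows are image rows top-to-bottom -> [x, y] with y up
    gray <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
    maxval <- max(1, max(gray))
  } else if (ext %in% c("pgm", "ppm", "pbm", "pnm")) {
    r <- read_pnm(path)
    gray3 <- r$img
    gray <- apply(gray3, c(1, 2), mean)  # channel mean
    gray <- gray[, rev(seq_len(ncol(gray))), drop = FALSE]  # y up
    maxval <- r$maxval
  } else {
    stop("unsupported raster extension '.", ext,
         "': supported are PGM/PPM/PBM and CSV/TSV matrices")
  }
  if (length(dim(gray)) != 2) stop("image is not 2D after channel reduction")
  if (auto_threshold) {
    thr <- otsu_threshold(gray)
  } else {
    if (threshold <= 0 || threshold >= 1)
      stop("threshold must lie in (0, 1)")
    thr <- threshold * maxval
  }
  px <- matrix(as.integer(gray > thr), nrow(gray), ncol(gray))
  vessel_mask(px, pixel_size, roi = roi)
}

#' Otsu threshold of a grayscale matrix
#'
#' Maximizes between-class variance over a 256-bin histogram.
#' @param gray numeric matrix of intensities.
#' @return the threshold intensity (same scale as `gray`).
#' @export
otsu_threshold <- function(gray) {
  v <- as.numeric(gray)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - lo) / (hi - lo) * nb)), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  kstar <- which.max(sigma_b)
  lo + (kstar / nb) * (hi - lo)
}

#' Resample a mask to a new pixel size (nearest neighbour)
#'
#' Used to bring an image to the solver grid spacing before 3D
#' reconstruction, which requires the mask pixel size and grid spacing
#' to be equal.
#'
#' @param mask a [vessel_mask()].
#' @param new_pixel_size target micrometres per pixel.
#' @return a [vessel_mask()] at the new resolution.
#' @export
resample_mask <- function(mask, new_pixel_size) {
  stopifnot(inherits(mask, "vessel_mask"), new_pixel_size > 0)
  d <- dim(mask$pixels)
  L <- d * mask$pixel_size
  nd <- pmax(1L, as.integer(round(L / new_pixel_size)))
  # nearest source pixel for each target pixel center
  ix <- pmin(d[1], pmax(1L, as.integer(
    ceiling(((seq_len(nd[1]) - 0.5) * new_pixel_size) / mask$pixel_size))))
  iy <- pmin(d[2], pmax(1L, as.integer(
    ceiling(((seq_len(nd[2]) - 0.5) * new_pixel_size) / mask$pixel_size))))
  px <- mask$pixels[ix, iy, drop = FALSE]
  roi <- if (is.null(mask$roi)) NULL else mask$roi[ix, iy, drop = FALSE]
  if (!is.null(roi)) roi[px == 1L] <- 1L
  vessel_mask(px, new_pixel_size, roi = roi)
}
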