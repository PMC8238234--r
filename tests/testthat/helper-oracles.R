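# Independent brute-force oracles.  These deliberately avoid the
# package's own transforms: plain loops / outer products over small
# inputs.

# squared Euclidean distance (in pixels) from every pixel to the nearest
# TRUE pixel; Inf when none
brute_dist2 <- function(sites) {
  d <- dim(sites)
  idx <- which(sites, arr.ind = TRUE)
  out <- matrix(Inf, d[1], d[2])
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j] <- min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)
  out
}

# exhaustive union-of-spheres occupancy: lumen pixel p (1-based, pixel
# units) with radius r_px[p]; voxel centers on the same x-y lattice and
# integer z offsets m.  Squared radii are snapped to integers when they
# are integers mathematically (pixel distance transforms), so the
# strict inequality breaks ties exactly.
brute_occupancy <- function(r_px, mmax) {
  d <- dim(r_px)
  idx <- which(r_px > 0, arr.ind = TRUE)
  r2 <- r_px[idx]^2
  near <- abs(r2 - round(r2)) < 1e-6 * pmax(1, r2)
  r2[near] <- round(r2[near])
  occ <- array(FALSE, c(d[1], d[2], 2 * mmax + 1))
  for (m in -mmax:mmax)
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2])) {
        dd <- (idx[, 1] - i)^2 + (idx[, 2] - j)^2 + m^2
        occ[i, j, m + mmax + 1] <- any(dd < r2)
      }
  occ
}

# exhaustive signed distance between voxel centers (units of spacing)
brute_sdf <- function(vox) {
  d <- dim(vox)
  lum <- which(vox == 1L, arr.ind = TRUE)
  tis <- which(vox == 0L, arr.ind = TRUE)
  phi <- array(NA_real_, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        if (vox[i, j, k] == 1L) {
          phi[i, j, k] <- -sqrt(min((tis[, 1] - i)^2 + (tis[, 2] - j)^2 +
                                      (tis[, 3] - k)^2))
        } else {
          phi[i, j, k] <- sqrt(min((lum[, 1] - i)^2 + (lum[, 2] - j)^2 +
                                     (lum[, 3] - k)^2))
        }
      }
  phi
}

# 8-neighbour counts by direct enumeration
brute_degrees <- function(px) {
  d <- dim(px)
  out <- matrix(NA_integer_, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      if (!px[i, j]) next
      cnt <- 0L
      for (a in -1:1) for (b in -1:1) {
        if (a == 0 && b == 0) next
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && px[ii, jj])
          cnt <- cnt + 1L
      }
      out[i, j] <- cnt
    }
  out
}

# unique-pair 8-adjacency step length (pixel units) by enumeration
brute_length_px <- function(px) {
  d <- dim(px)
  len <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      if (!px[i, j]) next
      # count each pair once: only E, N, NE, NW offsets
      for (off in list(c(1L, 0L, 1), c(0L, 1L, 1),
                       c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
        ii <- i + off[1]; jj <- j + off[2]
        if (ii >= 1 && ii <= d[1] && jj <= d[2] && px[ii, jj])
          len <- len + off[3]
      }
    }
  len
}

# 8-connected foreground components
count_components8 <- function(px) {
  d <- dim(px)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  for (i0 in seq_len(d[1]))
    for (j0 in seq_len(d[2])) {
      if (!px[i0, j0] || lab[i0, j0] > 0L) next
      cur <- cur + 1L
      stack <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(stack)) {
        q <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (a in -1:1) for (b in -1:1) {
          ii <- q[1] + a; jj <- q[2] + b
          if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
              px[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  cur
}

# holes: 4-connected background components not touching the border
count_holes <- function(px) {
  bg <- px == 0L
  d <- dim(bg)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  touches <- logical(0)
  for (i0 in seq_len(d[1]))
    for (j0 in seq_len(d[2])) {
      if (!bg[i0, j0] || lab[i0, j0] > 0L) next
      cur <- cur + 1L
      tb <- FALSE
      stack <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(stack)) {
        q <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (q[1] == 1 || q[2] == 1 || q[1] == d[1] || q[2] == d[2])
          tb <- TRUE
        for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- q[1] + off[1]; jj <- q[2] + off[2]
          if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
              bg[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
      touches <- c(touches, tb)
    }
  sum(!touches)
}

# random blob mask (connected-ish smooth threshold field)
random_blob <- function(nx, ny, seed, density = 0.4) {
  set.seed(seed)
  f <- matrix(stats::rnorm(nx * ny), nx, ny)
  # crude smoothing by repeated neighbour averaging
  for (it in 1:6) {
    g <- f
    g[-1, ] <- g[-1, ] + f[-nx, ]
    g[-nx, ] <- g[-nx, ] + f[-1, ]
    g[, -1] <- g[, -1] + f[, -ny]
    g[, -ny] <- g[, -ny] + f[, -1]
    f <- g / 5
  }
  thr <- stats::quantile(f, 1 - density)
  m <- matrix(as.integer(f > thr), nx, ny)
  m[1, ] <- 0L; m[nx, ] <- 0L; m[, 1] <- 0L; m[, ny] <- 0L
  m
}
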