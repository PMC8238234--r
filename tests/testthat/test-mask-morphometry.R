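test_that("load_mask binarizes PGM rasters at a fixed threshold", {
  tmp <- withr::local_tempdir()
  # all-black, all-white, and half/half images written without the
  # package's own writer
  nx <- 8; ny <- 6
  write_ascii_pgm <- function(path, vals) {
    rows <- apply(vals, 1, paste, collapse = " ")  # vals[row, col]
    writeLines(c("P2", paste(nx, ny), "255", rows), path)
  }
  black <- matrix(0L, ny, nx)
  white <- matrix(255L, ny, nx)
  half <- cbind(matrix(0L, ny, nx / 2), matrix(255L, ny, nx / 2))
  write_ascii_pgm(file.path(tmp, "black.pgm"), black)
  write_ascii_pgm(file.path(tmp, "white.pgm"), white)
  write_ascii_pgm(file.path(tmp, "half.pgm"), half)

  mb <- load_mask(file.path(tmp, "black.pgm"), pixel_size = 2)
  expect_true(all(mb$pixels == 0L))
  expect_equal(dim(mb$pixels), c(nx, ny))
  mw <- load_mask(file.path(tmp, "white.pgm"), pixel_size = 2)
  expect_true(all(mw$pixels == 1L))
  mh <- load_mask(file.path(tmp, "half.pgm"), pixel_size = 2,
                  threshold = 0.5)
  # left half of the image (x <= nx/2) is black, right half white
  expect_true(all(mh$pixels[1:(nx / 2), ] == 0L))
  expect_true(all(mh$pixels[(nx / 2 + 1):nx, ] == 1L))
  expect_equal(sum(mh$pixels), ny * nx / 2)  # direct pixel-count oracle
})

test_that("load_mask handles CSV matrices, RGB channel means and errors", {
  tmp <- withr::local_tempdir()
  m <- matrix(c(10, 250, 30, 240), 2, 2)
  write.table(m, file.path(tmp, "m.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  mk <- load_mask(file.path(tmp, "m.csv"), pixel_size = 1, threshold = 0.5)
  expect_equal(sum(mk$pixels), 2)
  # PPM: channel mean decides; pixel 1 mean (255+0+0)/3 = 85 < 127.5
  writeLines(c("P3", "2 1", "255",
               "255 0 0   200 200 200"), file.path(tmp, "c.ppm"))
  mc <- load_mask(file.path(tmp, "c.ppm"), pixel_size = 1)
  expect_identical(as.integer(mc$pixels), c(0L, 1L))
  expect_error(load_mask(file.path(tmp, "absent.pgm"), 1), "cannot read")
  writeLines("junk", file.path(tmp, "x.xyz"))
  expect_error(load_mask(file.path(tmp, "x.xyz"), 1), "unsupported")
  writeLines(c("P2", "2 2", "255", "0 0", "0 0"), file.path(tmp, "t.pgm"))
  expect_error(load_mask(file.path(tmp, "t.pgm"), 1, threshold = 1.2),
               "threshold")
})

test_that("binary P5 rasters and Otsu thresholding work", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "b.pgm")
  con <- file(path, "wb")
  writeChar("P5\n4 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(0, 0, 200, 210, 0, 5, 220, 190)), con)
  close(con)
  m <- load_mask(path, pixel_size = 1)
  expect_equal(sum(m$pixels), 4)
  mo <- load_mask(path, pixel_size = 1, auto_threshold = TRUE)
  expect_equal(sum(mo$pixels), 4)  # bimodal: Otsu separates the modes
})

test_that("vessel_mask validates its invariants", {
  px <- matrix(0L, 4, 4); px[2, 2] <- 1L
  expect_s3_class(vessel_mask(px, 1.51), "vessel_mask")
  expect_error(vessel_mask(px * 2L, 1), "binary")
  expect_error(vessel_mask(px, -1), "pixel_size")
  roi <- matrix(0L, 4, 4)
  expect_error(vessel_mask(px, 1, roi = roi), "roi")
  roi[2, 2] <- 1L
  expect_s3_class(vessel_mask(px, 1, roi = roi), "vessel_mask")
})

test_that("vascular density: forced arithmetic, counting oracle, roi", {
  bar <- matrix(0L, 100, 100)
  bar[, 1:20] <- 1L  # 20 x 100 solid bar
  expect_equal(vascular_density(vessel_mask(bar, 1)), 20.0)
  expect_equal(vascular_density(vessel_mask(matrix(0L, 10, 10), 1)), 0.0)
  set.seed(42)
  rnd <- matrix(rbinom(50 * 40, 1, 0.3), 50, 40)
  expect_equal(vascular_density(vessel_mask(rnd, 1)),
               100 * sum(rnd) / (50 * 40))
  roi <- matrix(0L, 100, 100); roi[, 1:50] <- 1L
  expect_equal(vascular_density(vessel_mask(bar, 1, roi = roi)),
               100 * sum(bar) / sum(roi))
})

test_that("skeletonization: bars, single pixels, crossing bars", {
  bar <- matrix(0L, 40, 20); bar[5:35, 9:11] <- 1L
  sk <- skeletonize_mask(vessel_mask(bar, 1))
  used <- which(sk$pixels == 1L, arr.ind = TRUE)
  expect_equal(unique(used[, 2]), 10)          # one-pixel-wide line
  expect_true(all(sk$pixels <= bar))           # skeleton within lumen
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  expect_equal(skeletonize_mask(vessel_mask(single, 1))$pixels, single)
  # crossing 3-wide bars thin to the one-pixel cross (thinning may
  # erode a couple of pixels at each free arm tip)
  p <- matrix(0L, 41, 41); p[, 20:22] <- 1L; p[20:22, ] <- 1L
  skp <- skeletonize_mask(vessel_mask(p, 1))$pixels
  ideal <- matrix(0L, 41, 41); ideal[, 21] <- 1L; ideal[21, ] <- 1L
  expect_true(all(skp <= ideal))
  expect_true(all(skp[3:39, 21] == 1L))
  expect_true(all(skp[21, 3:39] == 1L))
  # with the 8-connectivity branch definition the cross center and its
  # four arm pixels all have degree >= 3; the crossing is one junction
  nb <- brute_degrees(skp == 1L)
  expect_equal(sum(nb >= 3, na.rm = TRUE), 5)
  expect_equal(sum(nb == 4, na.rm = TRUE), 5)
})

test_that("skeletons of random blobs are thin subsets preserving topology", {
  for (seed in c(3, 17, 99)) {
    blob <- random_blob(48, 40, seed)
    mask <- vessel_mask(blob, 1)
    sk <- skeletonize_mask(mask)$pixels
    expect_true(all(sk <= blob))
    # no fully set 2x2 block
    blk <- sk[-48, -40] & sk[-1, -40] & sk[-48, -1] & sk[-1, -1]
    expect_false(any(blk))
    # same number of 8-connected components
    expect_equal(count_components8(sk == 1L), count_components8(blob == 1L))
  }
})

test_that("vessel length density follows the counting oracle", {
  line <- matrix(0L, 100, 100); line[1:100, 50] <- 1L
  mask <- vessel_mask(line, 1)
  sk <- structure(list(pixels = line, pixel_size = 1),
                  class = "skeleton_mask")
  expect_equal(vessel_length_density(sk, mask), 1.0)
  empty <- structure(list(pixels = line * 0L, pixel_size = 1),
                     class = "skeleton_mask")
  expect_equal(vessel_length_density(empty, mask), 0.0)
  blob <- random_blob(30, 30, 5)
  m2 <- vessel_mask(blob, 1)
  s2 <- skeletonize_mask(m2)
  expect_equal(vessel_length_density(s2, m2),
               100 * sum(s2$pixels) / (30 * 30))
})

test_that("branching index: line, Y-junction, lattice oracle", {
  # straight 1000-px line at 1 um/px
  line <- matrix(0L, 1000, 3); line[, 2] <- 1L
  sk <- structure(list(pixels = line, pixel_size = 1),
                  class = "skeleton_mask")
  bi <- branching_index(sk)
  expect_equal(bi$n_branch_points, 0)
  expect_equal(bi$total_length, 0.999)
  expect_equal(bi$branching_index, 0)
  expect_false(bi$degenerate)
  # ideal Y: north arm plus two diagonal arms -> exactly one branch point
  y <- matrix(0L, 21, 21)
  y[11, 11:20] <- 1L                       # north arm
  for (t in 1:9) { y[11 - t, 11 - t] <- 1L; y[11 + t, 11 - t] <- 1L }
  sy <- structure(list(pixels = y, pixel_size = 1),
                  class = "skeleton_mask")
  expect_equal(branching_index(sy)$n_branch_points, 1)
  # synthetic lattice vs brute-force enumeration oracle
  lat <- matrix(0L, 25, 25)
  lat[seq(3, 23, by = 5), 3:23] <- 1L
  lat[3:23, seq(3, 23, by = 5)] <- 1L
  sl <- structure(list(pixels = lat, pixel_size = 2),
                  class = "skeleton_mask")
  bl <- branching_index(sl)
  deg <- brute_degrees(lat == 1L)
  expect_equal(bl$n_branch_points, sum(deg >= 3, na.rm = TRUE))
  expect_equal(bl$total_length, brute_length_px(lat == 1L) * 2 / 1000)
  expect_equal(bl$branching_index, bl$n_branch_points / bl$total_length)
  # degenerate: single-pixel skeleton has zero length, flagged
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  so <- structure(list(pixels = one, pixel_size = 1),
                  class = "skeleton_mask")
  bo <- branching_index(so)
  expect_true(bo$degenerate)
  expect_equal(bo$branching_index, 0)
})

test_that("welding an extra branch strictly increases the index", {
  base <- matrix(0L, 40, 20); base[2:39, 10] <- 1L
  sk0 <- structure(list(pixels = base, pixel_size = 1),
                   class = "skeleton_mask")
  welded <- base
  for (t in 1:6) welded[20 + t, 10 + t] <- 1L
  sk1 <- structure(list(pixels = welded, pixel_size = 1),
                   class = "skeleton_mask")
  b0 <- branching_index(sk0); b1 <- branching_index(sk1)
  expect_gt(b1$branching_index, b0$branching_index)
  # the weld creates a junction cluster: under the per-pixel >= 3
  # neighbour definition the diagonal attachment marks several pixels
  expect_gte(b1$n_branch_points, 1)
  expect_equal(b0$n_branch_points, 0)
})

test_that("densities are invariant under rotations and mirroring", {
  blob <- random_blob(36, 28, 12)
  variants <- list(blob,
                   t(blob)[, rev(seq_len(36))],            # 90 deg
                   blob[rev(seq_len(36)), rev(seq_len(28))],  # 180 deg
                   blob[rev(seq_len(36)), ],               # mirror x
                   blob[, rev(seq_len(28))])               # mirror y
  vd <- vapply(variants, function(m) vascular_density(vessel_mask(m, 1)),
               numeric(1))
  expect_true(all(abs(vd - vd[1]) < 1e-12))
  ld <- vapply(variants, function(m) {
    mk <- vessel_mask(m, 1)
    vessel_length_density(skeletonize_mask(mk), mk)
  }, numeric(1))
  # thinning is orientation-dependent pixel-by-pixel but the length
  # density must agree closely across symmetries
  expect_true(all(abs(ld - ld[1]) / ld[1] < 0.08))
  # and vascular density dominates length density
  expect_true(all(vd > ld))
})

test_that("morphometry report is internally consistent and round-trips", {
  blob <- random_blob(40, 40, 8)
  rep <- morphometry(vessel_mask(blob, 1.51))
  expect_equal(rep$branching_index,
               rep$n_branch_points / rep$total_length)
  expect_true(rep$vascular_density >= rep$vessel_length_density)
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- write_morphometry_csv(rep, tmp, sample_id = "blob8")
  back <- read.csv(tmp)
  expect_equal(back$vascular_density, rep$vascular_density)
  expect_equal(back$sample_id, "blob8")
  expect_equal(back$total_length_mm, rep$total_length)
})
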