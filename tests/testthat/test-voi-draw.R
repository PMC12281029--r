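test_that("pen strokes match the exhaustive point-to-segment oracle", {
  voi <- empty_voi_on(c(20, 20, 6))
  line <- matrix(c(5, 10, 9, 10), ncol = 2, byrow = TRUE)
  v <- pen_stroke(voi, 3, line, thickness = 1)
  expect_equal(sum(v$mask), 5)                       # 5-voxel horizontal line
  expect_true(all(which(v$mask == 1L, arr.ind = TRUE)[, 3] == 4L))
  v0 <- pen_stroke(v, 3, line, thickness = 1, erase = TRUE)
  expect_equal(sum(v0$mask), 0)                      # draw then erase = empty
  set.seed(42)
  for (trial in seq_len(25)) {
    npts <- sample(1:4, 1)
    poly <- matrix(stats::runif(npts * 2, 0, 15), ncol = 2)
    th <- stats::runif(1, 1, 5)
    got <- pen_stroke(voi, 2, poly, thickness = th)
    want <- oracle_stroke_mask(c(20, 20), poly, th)
    expect_identical(got$mask[, , 3] == 1L, want)
  }
  expect_vv_error(pen_stroke(voi, 99, line), "vv_validation_error")
})

test_that("ellipses match brute-force membership and morphology identities", {
  voi <- empty_voi_on(c(24, 24, 4))
  r <- 4
  circ <- draw_ellipse(voi, 1, list(min = c(6, 6), max = c(6 + 2 * r, 6 + 2 * r)))
  brute <- sum(outer(-24:24, -24:24, function(x, y) x^2 + y^2 <= r^2))
  expect_equal(sum(circ$mask), brute)
  # outline equals filled minus eroded-filled
  outline <- draw_ellipse(voi, 1, list(min = c(6, 6), max = c(14, 14)),
                          filled = FALSE)
  filled <- draw_ellipse(voi, 1, list(min = c(6, 6), max = c(14, 14)))
  pl <- filled$mask[, , 2] == 1L
  er <- pl & rbind(pl[-1, ], FALSE) & rbind(FALSE, pl[-nrow(pl), ]) &
        cbind(pl[, -1], FALSE) & cbind(FALSE, pl[, -ncol(pl)])
  expect_identical(outline$mask[, , 2] == 1L, pl & !er)
  # erase over the identical ellipse clears it
  gone <- draw_ellipse(filled, 1, list(min = c(6, 6), max = c(14, 14)),
                       erase = TRUE)
  expect_equal(sum(gone$mask), 0)
  expect_vv_error(draw_ellipse(voi, 1, list(min = c(3, 3), max = c(3, 9))),
                  "vv_validation_error")
})

test_that("bucket fill equals a BFS reference and respects boundaries", {
  voi <- empty_voi_on(c(20, 20, 4))
  ring <- draw_ellipse(voi, 2, list(min = c(4, 4), max = c(15, 15)),
                       filled = FALSE)
  filled <- bucket_fill(ring, 2, c(9, 9))
  want <- oracle_flood(ring$mask[, , 3], c(9, 9))
  expect_identical(filled$mask[, , 3] == 1L, (ring$mask[, , 3] == 1L) | want)
  # exterior untouched
  expect_equal(filled$mask[1, 1, 3], 0L)
  # seed outside any contour floods the whole background of the slice
  open_fill <- bucket_fill(ring, 2, c(0, 0))
  expect_true(all(open_fill$mask[, , 3][ring$mask[, , 3] == 0L &
                                          oracle_flood(ring$mask[, , 3], c(0, 0))] == 1L))
  # a seed on a set voxel is a no-op with a notice
  idx <- which(ring$mask[, , 3] == 1L, arr.ind = TRUE)[1, ]
  expect_message(same <- bucket_fill(ring, 2, idx - 1L), "already set")
  expect_identical(same$mask, ring$mask)
  set.seed(9)
  for (trial in seq_len(25)) {
    plane_voi <- empty_voi_on(c(12, 12, 2))
    m <- plane_voi$mask
    m[, , 1] <- random_mask(12, 12, 0.35)
    plane_voi <- new_voi(m, affine = plane_voi$affine)
    zeros <- which(plane_voi$mask[, , 1] == 0L, arr.ind = TRUE)
    seed_ij <- zeros[sample(nrow(zeros), 1), ] - 1L
    got <- bucket_fill(plane_voi, 0, seed_ij)
    want <- oracle_flood(plane_voi$mask[, , 1], seed_ij)
    expect_identical(got$mask[, , 1] == 1L,
                     (plane_voi$mask[, , 1] == 1L) | want)
  }
})

test_that("intensity growing equals a flood oracle over the thresholded volume", {
  two <- make_phantom(phantom_spec(shape = c(18, 18, 18), primitives = list(
    list(kind = "sphere", center = c(5, 5, 5), radius = 2.5, intensity = 70),
    list(kind = "sphere", center = c(13, 13, 13), radius = 2.5, intensity = 70))))
  g <- intensity_grow(two, c(5, 5, 5), 60, 80)
  expect_equal(g$mask[6, 6, 6], 1L)
  expect_equal(g$mask[14, 14, 14], 0L)       # disconnected twin blob excluded
  expect_identical(g$mask == 1L, oracle_grow(two$data, c(5, 5, 5), 60, 80))
  # uniform volume with a full range grows everywhere
  uni <- new_volume(array(7, c(5, 5, 5)))
  expect_true(all(intensity_grow(uni, c(2, 2, 2), 0, 10)$mask == 1L))
  expect_vv_error(intensity_grow(two, c(0, 0, 0), 60, 80), "vv_validation_error")
  # randomized comparisons, both connectivities
  set.seed(5)
  for (trial in seq_len(12)) {
    noisy <- make_phantom(phantom_spec(shape = c(9, 9, 9), noise_sigma = 1,
                                       seed = trial))
    seedv <- c(4, 4, 4)
    lo <- noisy$data[5, 5, 5] - 0.8
    hi <- noisy$data[5, 5, 5] + 0.8
    for (conn in c(6, 26)) {
      got <- intensity_grow(noisy, seedv, lo, hi, connectivity = conn)
      expect_identical(got$mask == 1L,
                       oracle_grow(noisy$data, seedv, lo, hi, conn))
    }
  }
})

test_that("morphology is extensive/anti-extensive, idempotent, and exact on a point", {
  voi <- empty_voi_on(c(15, 15, 15))
  m <- voi$mask; m[7:9, 7:9, 7:9] <- 1L; m[8, 8, 11] <- 1L
  voi <- new_voi(m, affine = voi$affine)
  d <- morph_voi(voi, "dilate", 1)
  e <- morph_voi(voi, "erode", 1)
  expect_true(all(d$mask >= voi$mask))
  expect_true(all(e$mask <= voi$mask))
  cl <- morph_voi(voi, "close", 1)
  expect_identical(morph_voi(cl, "close", 1)$mask, cl$mask)
  op <- morph_voi(voi, "open", 1)
  expect_identical(morph_voi(op, "open", 1)$mask, op$mask)
  point <- empty_voi_on(c(9, 9, 9))
  pm <- point$mask; pm[5, 5, 5] <- 1L
  point <- new_voi(pm, affine = point$affine)
  expect_equal(sum(morph_voi(point, "dilate", 1)$mask), 7)  # 6-connected ball
})

test_that("2D operations touch only the addressed slice", {
  voi <- empty_voi_on(c(16, 16, 8))
  m <- voi$mask
  set.seed(3)
  for (k in seq_len(8)) m[, , k] <- random_mask(16, 16, 0.2)
  voi <- new_voi(m, affine = voi$affine)
  hashes_before <- vapply(seq_len(8), function(k)
    digest_slice(voi$mask[, , k]), character(1))
  ops <- list(
    function(v) pen_stroke(v, 4, matrix(c(2, 2, 10, 10), 2, byrow = TRUE), 2),
    function(v) draw_ellipse(v, 4, list(min = c(3, 3), max = c(9, 9))),
    function(v) paste_slice(v, 4, copy_slice(v, 1)))
  for (op in ops) {
    out <- op(voi)
    hashes_after <- vapply(seq_len(8), function(k)
      digest_slice(out$mask[, , k]), character(1))
    expect_identical(hashes_after[-5], hashes_before[-5])
  }
})

test_that("copy/paste buffers do not alias the source slice", {
  voi <- empty_voi_on(c(10, 10, 5))
  src <- draw_ellipse(voi, 1, list(min = c(2, 2), max = c(7, 7)))
  buf <- copy_slice(src, 1)
  pasted <- paste_slice(src, 3, buf)
  expect_identical(pasted$mask[, , 4], pasted$mask[, , 2])
  expect_identical(paste_slice(src, 1, copy_slice(src, 1))$mask, src$mask)
  # modifying the pasted slice leaves the source untouched
  modified <- pen_stroke(pasted, 3, matrix(c(0, 0), 1), thickness = 2)
  expect_identical(modified$mask[, , 2], src$mask[, , 2])
  expect_vv_error(paste_slice(src, 1, matrix(0L, 3, 3)), "vv_validation_error")
})

test_that(".voi persistence is gzipped NIfTI readable by an independent reader", {
  skip_if_not_installed("RNifti")
  voi <- empty_voi_on(c(12, 12, 6))
  voi <- draw_ellipse(voi, 2, list(min = c(2, 2), max = c(8, 8)))
  path <- withr::local_tempfile(fileext = ".voi")
  save_voi(voi, path)
  expect_equal(readBin(path, "raw", n = 2), as.raw(c(0x1f, 0x8b)))
  back <- load_voi(path)
  expect_identical(back$mask, voi$mask)
  expect_lt(max(abs(back$affine - voi$affine)), 1e-5)
  # byte-identical file with a .nii.gz name loads in a general NIfTI reader
  nii_path <- paste0(path, ".nii.gz")
  file.copy(path, nii_path)
  ref <- RNifti::readNifti(nii_path)
  expect_equal(sum(ref), sum(voi$mask))
  expect_identical(array(as.integer(ref), dim = dim(ref)), voi$mask)
})
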