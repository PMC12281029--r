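test_that("incidence fractions are exact per-voxel subject means", {
  grid <- tiny_phantom(shape = c(16, 16, 12))
  lesions <- make_lesion_set(10, grid, seed = 21, radius_range = c(1.5, 3))
  map <- incidence_map(lesions)
  expect_equal(map$n_subjects, 10)
  counts <- Reduce(`+`, lapply(lesions, `[[`, "mask"))
  expect_identical(map$fraction, counts / 10)
  expect_true(all(map$fraction >= 0 & map$fraction <= 1))
  # counting oracle: sum(fraction) * n equals total lesioned voxels
  expect_equal(sum(map$fraction) * 10, sum(vapply(lesions, function(v)
    sum(v$mask), numeric(1))))
  # single VOI: fraction equals the mask
  expect_identical(incidence_map(lesions[1])$fraction, lesions[[1]]$mask + 0)
})

test_that("incidence is permutation-invariant and dilutes exactly with empty VOIs", {
  grid <- tiny_phantom(shape = c(12, 12, 12))
  lesions <- make_lesion_set(6, grid, seed = 4, radius_range = c(1.5, 2.5))
  m1 <- incidence_map(lesions)
  m2 <- incidence_map(rev(lesions))
  expect_identical(m1$fraction, m2$fraction)
  with_empty <- incidence_map(c(lesions, list(new_voi(reference = grid))))
  expect_equal(with_empty$fraction, m1$fraction * 6 / 7)
})

test_that("mismatched grids are rejected with the offending input named", {
  grid <- tiny_phantom(shape = c(10, 10, 10))
  a <- make_lesion_set(1, grid, seed = 1, radius_range = c(2, 2))[[1]]
  other <- new_voi(reference = make_phantom(phantom_spec(shape = c(8, 8, 8))))
  expect_error(incidence_map(list(a, other)), "VOI 2")
  shift <- rbind(cbind(diag(3), c(5, 0, 0)), c(0, 0, 0, 1))
  moved <- new_voi(a$mask, affine = a$affine %*% shift)
  expect_error(incidence_map(list(a, moved)), "VOI 2")
})

test_that("the incidence overlay reproduces the 1%/10% display thresholds", {
  frac <- array(0, dim = c(4, 4, 1))
  frac[1, 1, 1] <- 0.005
  frac[2, 1, 1] <- 0.01
  frac[3, 1, 1] <- 0.10
  frac[4, 1, 1] <- 0.5
  map <- structure(list(fraction = frac, n_subjects = 200, affine = diag(4)),
                   class = "vv_incidence")
  layer <- incidence_overlay(map)
  expect_equal(layer$display_min, 0.01)
  expect_equal(layer$display_max, 0.10)
  norm <- window_intensity(frac, layer$display_min, layer$display_max)
  rgba <- apply_lut(norm[, , 1], layer$lut)
  alpha <- rgba[, , 4]
  alpha[frac[, , 1] < layer$display_min] <- 0L
  expect_equal(alpha[1, 1], 0L)                            # 0.5% -> transparent
  expect_equal(as.numeric(rgba[2, 1, 1:3]), as.numeric(layer$lut[1, 1:3]))    # 1% -> cold end
  expect_equal(as.numeric(rgba[3, 1, 1:3]), as.numeric(layer$lut[256, 1:3]))  # 10% -> warm end
  expect_equal(as.numeric(rgba[4, 1, 1:3]), as.numeric(layer$lut[256, 1:3]))  # saturates above
  # the default warm ramp really runs cold (blue) to warm (red)
  expect_gt(layer$lut[1, 3], layer$lut[1, 1])
  expect_gt(layer$lut[256, 1], layer$lut[256, 3])
  expect_vv_error(incidence_overlay(map, 0.2, 0.1), "vv_validation_error")
})

test_that("VOI descriptives match closed forms and a brute-force centroid", {
  grid1 <- make_phantom(phantom_spec(shape = c(8, 8, 8)))
  v <- new_voi(reference = grid1)
  v$mask[4, 5, 6] <- 1L
  d <- voi_descriptives(v)
  expect_equal(d$n_voxels, 1L)
  expect_equal(d$volume_mm3, 1)
  expect_equal(c(d$com_x, d$com_y, d$com_z), voxel_to_world(v, c(3, 4, 5)))
  grid2 <- make_phantom(phantom_spec(shape = c(8, 8, 8), voxel_size = c(2, 2, 2)))
  v2 <- new_voi(reference = grid2)
  v2$mask[3:4, 3:4, 3:4] <- 1L
  expect_equal(voi_descriptives(v2)$volume_mm3, 64)
  # brute-force centroid on a random mask
  set.seed(6)
  v3 <- new_voi(array(as.integer(stats::runif(512) < 0.2), dim = c(8, 8, 8)),
                reference = grid2)
  d3 <- voi_descriptives(v3)
  acc <- c(0, 0, 0); n <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) if (v3$mask[i, j, k] == 1L) {
    acc <- acc + voxel_to_world(v3, c(i, j, k) - 1)
    n <- n + 1
  }
  expect_equal(c(d3$com_x, d3$com_y, d3$com_z), acc / n, tolerance = 1e-12)
  # empty VOI is flagged
  d0 <- voi_descriptives(new_voi(reference = grid1))
  expect_true(d0$empty)
  expect_equal(d0$n_voxels, 0L)
  expect_true(is.na(d0$com_x))
})

test_that("descriptives CSVs round-trip with a stable column order", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptives_csv(list(), path)
  hdr <- readLines(path)
  expect_length(hdr, 1)
  expect_match(hdr, "^\"label\",\"n_voxels\",\"volume_mm3\"")
  grid <- make_phantom(phantom_spec(shape = c(8, 8, 8)))
  v <- new_voi(reference = grid); v$mask[2:3, 2:3, 2:3] <- 1L
  recs <- list(voi_descriptives(v, label = "a"),
               voi_descriptives(new_voi(reference = grid), label = "b"))
  write_descriptives_csv(recs, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$n_voxels, c(8L, 0L))
  expect_equal(back$volume_mm3[1], 8)
  expect_equal(names(back)[1:3], c("label", "n_voxels", "volume_mm3"))
})

test_that("incidence maps serialize as float32 NIfTI", {
  grid <- tiny_phantom(shape = c(10, 10, 10))
  lesions <- make_lesion_set(4, grid, seed = 11, radius_range = c(1.5, 2.5))
  map <- incidence_map(lesions)
  path <- withr::local_tempfile(fileext = ".nii")
  write_incidence(map, path)
  back <- read_volume(path)
  expect_equal(back$datatype, "float32")
  expect_equal(back$data, map$fraction, tolerance = 1e-7)
})
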