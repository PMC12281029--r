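test_that("voxel/world mapping applies the affine and inverts exactly", {
  vol <- new_volume(array(0, c(8, 8, 8)))
  expect_equal(voxel_to_world(vol, c(3, 4, 5)), c(3, 4, 5))
  vol2 <- new_volume(array(0, c(8, 8, 8)), voxel_size = c(2, 2, 2))
  expect_equal(voxel_to_world(vol2, c(1, 1, 1)), c(2, 2, 2))
  set.seed(11)
  A <- diag(4)
  A[1:3, 1:3] <- matrix(stats::rnorm(9), 3) + diag(3) * 3
  A[1:3, 4] <- stats::rnorm(3, sd = 20)
  volr <- new_volume(array(0, c(4, 4, 4)), affine = A)
  pts <- matrix(stats::runif(30, -5, 10), ncol = 3)
  back <- world_to_voxel(volr, voxel_to_world(volr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  # independent matrix-inverse oracle
  Minv <- solve(A[1:3, 1:3])
  w <- voxel_to_world(volr, c(1, 2, 3))
  expect_equal(world_to_voxel(volr, w),
               as.numeric(Minv %*% (w - A[1:3, 4])), tolerance = 1e-9)
  Abad <- A; Abad[1:3, 1] <- 0
  expect_vv_error(new_volume(array(0, c(2, 2, 2)), affine = Abad),
                  "vv_validation_error")
})

test_that("trilinear sampling is exact on grid points and linear ramps", {
  vol <- tiny_phantom(shape = c(9, 9, 9))
  pts <- as.matrix(expand.grid(0:8, 0:8, 0:8))
  vals <- sample_volume(vol, pts, "trilinear")
  expect_equal(vals, vol$data[pts + 1])
  ramp <- make_phantom(phantom_spec(shape = c(8, 8, 8), primitives = list(
    list(kind = "linear_gradient", direction = c(1, 0, 0), intensity = 1))))
  expect_equal(sample_volume(ramp, c(2.5, 0, 0), "trilinear"), 2.5)
  expect_equal(sample_volume(ramp, c(4.25, 3.5, 6.75), "trilinear"), 4.25,
               tolerance = 1e-9)
})

test_that("trilinear samples stay within the 8-neighbor min/max envelope", {
  vol <- make_phantom(phantom_spec(shape = c(12, 12, 12), noise_sigma = 5, seed = 2))
  set.seed(7)
  n <- 10000
  pts <- cbind(stats::runif(n, 0, 11), stats::runif(n, 0, 11), stats::runif(n, 0, 11))
  vals <- sample_volume(vol, pts, "trilinear")
  f <- floor(pmin(pts, 10))
  for (q in seq_len(200)) {     # exhaustive neighbor scan on a subsample
    nb <- numeric(0)
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
      nb <- c(nb, vol$data[f[q, 1] + di + 1, f[q, 2] + dj + 1, f[q, 3] + dk + 1])
    expect_gte(vals[q], min(nb) - 1e-9)
    expect_lte(vals[q], max(nb) + 1e-9)
  }
  # vectorized envelope over all 10^4 points
  lo <- hi <- NULL
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    v <- vol$data[cbind(f[, 1] + di + 1, f[, 2] + dj + 1, f[, 3] + dk + 1)]
    lo <- if (is.null(lo)) v else pmin(lo, v)
    hi <- if (is.null(hi)) v else pmax(hi, v)
  }
  expect_true(all(vals >= lo - 1e-9 & vals <= hi + 1e-9))
})

test_that("nearest sampling rounds half away from zero and fills 0 outside", {
  vol <- new_volume(array(seq_len(27), c(3, 3, 3)))
  expect_equal(sample_volume(vol, c(0.5, 0, 0), "nearest"),
               unname(vol$data[2, 1, 1]))
  expect_equal(sample_volume(vol, c(1.5, 1.5, 1.5), "nearest"),
               unname(vol$data[3, 3, 3]))
  expect_equal(sample_volume(vol, c(-3, 0, 0), "nearest"), 0)
  expect_equal(sample_volume(vol, c(0, 0, 99), "trilinear"), 0)
})

test_that("canonical_ras is idempotent, lossless, and fixes single flips", {
  vol <- tiny_phantom(shape = c(6, 8, 10), seed = 5, noise = 1)
  expect_identical(canonical_ras(vol)$data, vol$data)   # already RAS
  # LAS volume: x axis stored flipped
  las_aff <- vol$affine %*% diag(c(-1, 1, 1, 1))
  las_aff[1, 4] <- vol$affine[1, 4] + (dim(vol$data)[1] - 1) * vol$affine[1, 1]
  las <- new_volume(vol$data[dim(vol$data)[1]:1, , ], affine = las_aff)
  fixed <- canonical_ras(las)
  expect_identical(fixed$data, vol$data)
  expect_lt(max(abs(fixed$affine - vol$affine)), 1e-9)
  # axis permutation + flip: world positions and intensity multiset preserved
  perm <- new_volume(aperm(vol$data, c(3, 1, 2)),
                     affine = vol$affine[, c(3, 1, 2, 4)])
  canon <- canonical_ras(perm)
  expect_equal(sort(as.numeric(canon$data)), sort(as.numeric(vol$data)))
  idx <- rbind(c(0, 0, 0), c(2, 3, 4), c(5, 1, 2))
  for (r in seq_len(nrow(idx))) {
    w_old <- voxel_to_world(perm, idx[r, ])
    ijk_new <- world_to_voxel(canon, w_old)
    expect_lt(max(abs(ijk_new - round(ijk_new))), 1e-6)
    expect_equal(canon$data[matrix(round(ijk_new) + 1, 1)],
                 perm$data[matrix(idx[r, ] + 1, 1)])
  }
  expect_identical(canonical_ras(canon)$data, canon$data)
})

test_that("reslicing onto the source grid is the identity", {
  vol <- tiny_phantom(shape = c(7, 8, 9), voxel_size = c(1, 1.5, 2), noise = 1)
  tgt <- grid_spec(dim(vol$data), vol$affine)
  for (interp in c("trilinear", "nearest")) {
    rs <- reslice_world(vol, tgt, interp)
    expect_lt(max(abs(rs$data - vol$data)), 1e-9)
    expect_equal(rs$affine, vol$affine)
  }
})

test_that("trilinear reslice reproduces a linear field at finer resolution", {
  ramp <- make_phantom(phantom_spec(shape = c(9, 9, 9), primitives = list(
    list(kind = "linear_gradient", direction = c(1, 0, 0), intensity = 2))))
  up_aff <- diag(c(0.5, 0.5, 0.5, 1))
  up <- reslice_world(ramp, grid_spec(c(17, 17, 17), up_aff), "trilinear")
  g <- as.matrix(expand.grid(0:16, 0:16, 0:16))
  expected <- 2 * (g[, 1] * 0.5)
  expect_lt(max(abs(as.numeric(up$data) - expected)), 1e-6)
})

test_that("nearest-neighbor reslice never invents intensities", {
  vol <- make_phantom(phantom_spec(shape = c(8, 8, 8), noise_sigma = 3, seed = 4))
  th <- 0.4
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rs <- reslice_world(vol, grid_spec(c(12, 12, 12), rot), "nearest")
  expect_true(all(as.numeric(rs$data) %in% c(0, as.numeric(vol$data))))
})

test_that("rotate/unrotate error is smaller on smooth data than on noise", {
  th <- 25 * pi / 180
  rot <- diag(4); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  roundtrip_mae <- function(vol) {
    sh <- dim(vol$data)
    # rotated intermediate grid positioned to cover the whole source cube
    mid_aff <- rot
    mid_aff[1:3, 4] <- rot[1:3, 1:3] %*% c(-1, -6, -1)
    mid <- reslice_world(vol, grid_spec(sh + 8L, mid_aff), "trilinear")
    back <- reslice_world(mid, grid_spec(sh, vol$affine), "trilinear")
    interior <- vol$data[4:(sh[1] - 3), 4:(sh[2] - 3), 4:(sh[3] - 3)]
    bint <- back$data[4:(sh[1] - 3), 4:(sh[2] - 3), 4:(sh[3] - 3)]
    mean(abs(interior - bint))
  }
  smooth <- make_phantom(phantom_spec(shape = c(14, 14, 14), primitives = list(
    list(kind = "linear_gradient", direction = c(1, 1, 0), intensity = 3))))
  noisy <- make_phantom(phantom_spec(shape = c(14, 14, 14), noise_sigma = 10, seed = 8))
  expect_lt(roundtrip_mae(smooth), roundtrip_mae(noisy))
  expect_lt(roundtrip_mae(smooth), 1)
})
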