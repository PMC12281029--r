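make_suite <- function(dir, seed = 3) {
  spec <- phantom_spec(shape = c(9, 7, 5), voxel_size = c(1.2, 1, 2),
    primitives = list(list(kind = "sphere", center = c(4, 3, 2), radius = 2,
                           intensity = 50)),
    noise_sigma = 1, seed = seed)
  list(manifest = write_fixture_suite(dir, spec), vol = make_phantom(spec))
}

test_that("sniff_format recognizes each format from leading bytes", {
  dir <- withr::local_tempdir()
  s <- make_suite(dir)
  for (i in seq_len(nrow(s$manifest))) {
    path <- s$manifest$path[i]
    bytes <- readBin(path, "raw", n = min(file.size(path), 4096))
    expect_equal(sniff_format(bytes, path_hint = path), s$manifest$format[i])
  }
  expect_equal(sniff_format(raw(0)), "unknown")
  expect_equal(sniff_format(charToRaw("garbage that is not a volume")), "unknown")
  # gzip magic alone routes to the compressed branch
  gz_bytes <- readBin(s$manifest$path[2], "raw", n = 2)
  expect_equal(gz_bytes, as.raw(c(0x1f, 0x8b)))
  # NIfTI magic lives at offset 344
  nii_bytes <- readBin(s$manifest$path[1], "raw", n = 352)
  expect_equal(rawToChar(nii_bytes[345:347]), "n+1")
})

test_that("scl_slope/scl_inter scaling is applied on read (slope 0 means 1)", {
  dir <- withr::local_tempdir()
  vol <- new_volume(array(5, dim = c(2, 2, 2)), datatype = "int16")
  path <- file.path(dir, "scaled.nii")
  write_nifti(vol, path, gzipped = FALSE)
  # patch scl_slope = 2 and scl_inter = 10 at their standard header offsets
  con <- file(path, "r+b")
  seek(con, 112, rw = "write")
  writeBin(c(2, 10), con, size = 4L, endian = "little")
  close(con)
  v <- read_volume(path)
  expect_equal(unname(v$data[1, 1, 1]), 2 * 5 + 10)
  # and the unpatched file (slope written as 1) reads values verbatim
  write_nifti(vol, path, gzipped = FALSE)
  expect_equal(unname(read_volume(path)$data[1, 1, 1]), 5)
})

test_that("our NIfTI reader agrees with an independent reader (RNifti)", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  s <- make_suite(dir)
  ours <- read_volume(s$manifest$path[1])
  ref <- RNifti::readNifti(s$manifest$path[1])
  expect_equal(as.numeric(ours$data), as.numeric(ref), tolerance = 1e-7)
  xf <- structure(RNifti::xform(ref), dimnames = NULL)
  expect_lt(max(abs(xf[1:3, ] - ours$affine[1:3, ])), 1e-4)
  # slope/inter example cross-checked through RNifti as well
  expect_equal(unname(ours$data[5, 4, 3]), as.numeric(ref[5, 4, 3]), tolerance = 1e-7)
})

test_that("our MGH writer/reader agrees with an independent reader (nibabel)", {
  dir <- withr::local_tempdir()
  s <- make_suite(dir)
  mgh <- s$manifest$path[s$manifest$format == "mgh"]
  py <- sprintf(paste0(
    "import nibabel as nib, numpy as np\n",
    "img = nib.load('%s')\n",
    "d = np.asanyarray(img.dataobj).astype(np.float64)\n",
    "print(repr(float(d.sum()))); print(repr(float(np.abs(d).max())))\n",
    "print(' '.join(repr(float(x)) for x in img.affine.ravel()))\n"), mgh)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  expect_equal(as.numeric(out[1]), sum(s$vol$data), tolerance = 1e-6)
  expect_equal(as.numeric(out[2]), max(abs(s$vol$data)), tolerance = 1e-6)
  nb_aff <- matrix(as.numeric(strsplit(out[3], " ")[[1]]), 4, 4, byrow = TRUE)
  expect_lt(max(abs(nb_aff - s$vol$affine)), 1e-4)
})

test_that("big-endian MGH and little-endian NIfTI yield the same volume", {
  dir <- withr::local_tempdir()
  s <- make_suite(dir)
  nii <- read_volume(file.path(dir, "phantom.nii"))
  mgh <- read_volume(file.path(dir, "phantom.mgh"))
  expect_identical(nii$data, mgh$data)
  corners <- rbind(c(0, 0, 0), c(8, 6, 4))
  expect_lt(max(abs(voxel_to_world(nii, corners) - voxel_to_world(mgh, corners))),
            1e-3)
})

test_that("write_nifti round-trips exactly and encodes the affine in both forms", {
  dir <- withr::local_tempdir()
  # uint8 mask volume: bit-exact round trip
  mask <- array(as.integer(array(stats::runif(4 * 5 * 6), c(4, 5, 6)) > 0.5),
                dim = c(4, 5, 6))
  vol8 <- new_volume(mask, datatype = "uint8")
  p8 <- file.path(dir, "mask.nii")
  write_nifti(vol8, p8, gzipped = FALSE)
  expect_identical(read_volume(p8)$data, mask + 0)
  # gzipped output starts with the gzip magic
  pgz <- file.path(dir, "mask.nii.gz")
  write_nifti(vol8, pgz, gzipped = TRUE)
  expect_equal(readBin(pgz, "raw", n = 2), as.raw(c(0x1f, 0x8b)))
  # rotated affine survives the quaternion encode/decode (qform fallback)
  th <- 0.3
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot[1:3, 4] <- c(-5, 3, 7)
  volr <- new_volume(array(1, c(3, 3, 3)), affine = rot)
  pr <- file.path(dir, "rot.nii")
  write_nifti(volr, pr, gzipped = FALSE)
  con <- file(pr, "r+b")
  seek(con, 254, rw = "write")
  writeBin(0L, con, size = 2L, endian = "little")   # sform_code = 0: force qform path
  close(con)
  back <- read_volume(pr)
  expect_lt(max(abs(back$affine - rot)), 1e-5)
})

test_that("truncated and unknown files produce clear errors", {
  dir <- withr::local_tempdir()
  s <- make_suite(dir)
  p <- file.path(dir, "trunc.nii")
  bytes <- readBin(s$manifest$path[1], "raw", n = file.size(s$manifest$path[1]))
  writeBin(bytes[1:400], p)
  expect_vv_error(read_volume(p), "vv_corrupt_error")
  bad <- file.path(dir, "noise.bin")
  writeBin(as.raw(sample(0:255, 600, replace = TRUE)), bad)
  expect_error(read_volume(bad), class = "vv_error")
})

test_that("4D NIfTI inputs are truncated to the first volume with a warning", {
  dir <- withr::local_tempdir()
  expect_warning(v4 <- new_volume(array(seq_len(2 * 2 * 2 * 3), c(2, 2, 2, 3))),
                 "first volume")
  expect_equal(dim(v4$data), c(2L, 2L, 2L))
  expect_equal(as.numeric(v4$data), as.numeric(seq_len(8)))
})
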